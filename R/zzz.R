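.onLoad <- function(libname, pkgname) {
  register_default_hash_algorithms()
  register_broker("file",
                  new_broker = new_disk_broker,
                  dataset_uri = disk_dataset_uri,
                  list_datasets = disk_list_datasets)
  register_broker("mock",
                  new_broker = new_mock_broker,
                  dataset_uri = mock_dataset_uri,
                  list_datasets = mock_list_datasets)
  register_default_cli_commands()
}
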