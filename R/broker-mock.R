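# Object-store-like broker ("mock" scheme).
#
# Emulates the shape of remote object storage on a local directory so the
# identifier-keyed storage and caching code paths are exercised without a
# network. Datasets are addressed by UUID (mock://<store>/<uuid>), item bytes
# live flat under data/<identifier> -- there is no relpath-derived directory
# tree -- and each item's relative path is kept in a sidecar key
# (meta/<identifier>), mirroring how object-store backends keep the relpath in
# per-object metadata. Reading an item's content goes through a local cache
# directory, as it would for a genuinely remote medium.

new_mock_broker <- function(uri) {
  uri <- as_dt_uri(uri)
  loc <- sub("/+$", "", uri$location)
  structure(
    list(uri = uri, root = loc,
         store = dirname(loc), uuid = basename(loc)),
    class = c("dt_mock_broker", "dt_broker")
  )
}

mock_key_path <- function(broker, key) {
  file.path(broker$root, key)
}

#' @export
broker_create_structure.dt_mock_broker <- function(broker) {
  if (dir.exists(broker$root)) {
    stop_broker(sprintf("location already exists: %s", broker$uri$uri))
  }
  for (d in c("", "data", "meta")) {
    dir.create(file.path(broker$root, d), recursive = TRUE,
               showWarnings = FALSE)
  }
  structure_map <- list(
    admin_record = "admin",
    data = "data",
    item_meta = "meta",
    manifest = "manifest",
    overlays = "overlay.<name>",
    readme = "readme",
    structure_readme = "structure_readme"
  )
  write_text_file(mock_key_path(broker, "structure"),
                  structure_json(structure_map, broker_name = "mock"))
  write_text_file(
    mock_key_path(broker, "structure_readme"),
    paste0("Object-store representation of a dtoolr dataset.\n",
           "Items are stored flat under data/ keyed by identifier;\n",
           "metadata lives in flat key files. Do not edit by hand.\n")
  )
  invisible(broker)
}

#' @export
broker_exists.dt_mock_broker <- function(broker) {
  file.exists(mock_key_path(broker, "admin"))
}

#' @export
broker_location_occupied.dt_mock_broker <- function(broker) {
  dir.exists(broker$root)
}

#' @export
broker_put_text.dt_mock_broker <- function(broker, key, text) {
  path <- mock_key_path(broker, key)
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  write_text_file(path, text)
  invisible(broker)
}

#' @export
broker_get_text.dt_mock_broker <- function(broker, key) {
  path <- mock_key_path(broker, key)
  if (!file.exists(path)) {
    stop_not_found(sprintf("no '%s' artefact in dataset at %s", key,
                           broker$uri$uri))
  }
  read_text_file(path)
}

#' @export
broker_has_text.dt_mock_broker <- function(broker, key) {
  file.exists(mock_key_path(broker, key))
}

#' @export
broker_list_overlay_names.dt_mock_broker <- function(broker) {
  keys <- list.files(broker$root, pattern = "^overlay\\.")
  sort(sub("^overlay\\.", "", keys))
}

#' @export
broker_put_item.dt_mock_broker <- function(broker, src_path, relpath) {
  identifier <- generate_identifier(relpath)
  dest <- file.path(broker$root, "data", identifier)
  ok <- file.copy(src_path, dest, overwrite = TRUE, copy.date = TRUE)
  if (!ok) {
    stop_io(sprintf("failed to store '%s' as item '%s'", src_path, relpath))
  }
  write_text_file(file.path(broker$root, "meta", identifier), relpath)
  invisible(identifier)
}

#' @export
broker_stored_items.dt_mock_broker <- function(broker) {
  data_dir <- file.path(broker$root, "data")
  ids <- sort(list.files(data_dir))
  if (length(ids) == 0L) {
    return(data.frame(identifier = character(0), relpath = character(0),
                      size_in_bytes = numeric(0), utc_timestamp = numeric(0),
                      stringsAsFactors = FALSE))
  }
  relpaths <- vapply(ids, function(id) {
    sidecar <- file.path(broker$root, "meta", id)
    if (file.exists(sidecar)) read_text_file(sidecar) else NA_character_
  }, character(1), USE.NAMES = FALSE)
  info <- file.info(file.path(data_dir, ids))
  data.frame(
    identifier = ids,
    relpath = relpaths,
    size_in_bytes = as.numeric(info$size),
    utc_timestamp = as.numeric(info$mtime),
    stringsAsFactors = FALSE
  )
}

#' @export
broker_item_path.dt_mock_broker <- function(broker, identifier, relpath) {
  src <- file.path(broker$root, "data", identifier)
  if (!file.exists(src)) {
    stop_not_found(sprintf("item '%s' (%s) not present in dataset at %s",
                           identifier, relpath, broker$uri$uri))
  }
  cache_dir <- file.path(dt_cache_root(), broker$uuid)
  dir.create(cache_dir, recursive = TRUE, showWarnings = FALSE)
  # keep the relpath's extension chain so downstream tools that sniff
  # suffixes (gunzip and friends) still work on the cached copy
  ext <- sub("^[^.]*", "", basename(relpath))
  dest <- file.path(cache_dir, paste0(identifier, ext))
  if (!file.exists(dest)) {
    ok <- file.copy(src, dest, copy.date = TRUE)
    if (!ok) {
      stop_io(sprintf("failed to materialize item '%s' into cache", identifier))
    }
  }
  absolute_path(dest)
}

#' @export
broker_item_hash.dt_mock_broker <- function(broker, identifier, relpath,
                                            algorithm) {
  # hash the stored object, never the cache copy
  hash_file_content(file.path(broker$root, "data", identifier),
                    algorithm)$digest
}

mock_dataset_uri <- function(base_uri, name, uuid) {
  loc <- sub("/+$", "", base_uri$location)
  parse_uri(paste0("mock://", loc, "/", uuid))
}

mock_list_datasets <- function(base_uri) {
  store <- sub("/+$", "", base_uri$location)
  entries <- if (dir.exists(store)) {
    list.dirs(store, recursive = FALSE, full.names = TRUE)
  } else {
    character(0)
  }
  rows <- lapply(entries, function(d) {
    admin_path <- file.path(d, "admin")
    if (!file.exists(admin_path)) {
      return(NULL)
    }
    admin <- admin_from_json(read_text_file(admin_path))
    data.frame(name = admin$name,
               uri = paste0("mock://", store, "/", basename(d)),
               state = admin$state, stringsAsFactors = FALSE)
  })
  rows <- Filter(Negate(is.null), rows)
  if (length(rows) == 0L) {
    return(data.frame(name = character(0), uri = character(0),
                      state = character(0), stringsAsFactors = FALSE))
  }
  do.call(rbind, rows)
}
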