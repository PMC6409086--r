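# Core dataset lifecycle: create, add, freeze, load, fetch, verify, summarize.

test_that("creating a proto dataset lays out the expected disk structure", {
  local_dt_sandbox(creator = "olssont")
  base <- local_base_uri("file")
  proto <- create_proto_dataset("ds-name", base)
  root <- file.path(base, "ds-name")

  expect_true(dir.exists(file.path(root, "data")))
  expect_true(file.exists(file.path(root, ".dtool", "dtool")))
  expect_true(file.exists(file.path(root, ".dtool", "structure.json")))
  expect_true(file.exists(file.path(root, ".dtool", "README.txt")))
  expect_true(file.exists(file.path(root, "README.yml")))

  expect_identical(proto$admin$name, "ds-name")
  expect_identical(proto$admin$state, "proto")
  expect_identical(proto$admin$creator_username, "olssont")
  expect_match(proto$admin$uuid,
               "^[0-9a-f]{8}-[0-9a-f]{4}-[0-9a-f]{4}-[0-9a-f]{4}-[0-9a-f]{12}$")
})

test_that("successive creations yield distinct UUIDs; bad names rejected", {
  local_dt_sandbox()
  a <- create_proto_dataset("same-args", local_base_uri("file"))
  b <- create_proto_dataset("same-args", local_base_uri("file"))
  expect_false(a$admin$uuid == b$admin$uuid)

  expect_error(create_proto_dataset("bad name!", local_base_uri("file")),
               class = "dtoolr_validation_error")
})

test_that("adding items stores bytes, returns the relpath identifier and replaces on re-add", {
  local_dt_sandbox()
  base <- local_base_uri("file")
  proto <- create_proto_dataset("adder", base)

  f <- local_content_file("hello world\n")
  id <- add_item(proto, f, "hello.txt")
  expect_identical(id, generate_identifier("hello.txt"))
  expect_true(file.exists(file.path(base, "adder", "data", "hello.txt")))

  # default relpath is the source file name
  g <- file.path(withr::local_tempdir(), "named.txt")
  writeLines("x", g)
  expect_identical(add_item(proto, g), generate_identifier("named.txt"))

  # re-adding the same relpath replaces the content, not the identifier
  f2 <- local_content_file("replaced\n")
  expect_identical(add_item(proto, f2, "hello.txt"), id)
  ds <- freeze(proto)
  expect_identical(length(list_identifiers(ds)), 2L)
  expect_identical(readLines(fetch_item(ds, id)), "replaced")

  # lifecycle rule: frozen datasets reject additions
  expect_error(add_item(proto, f, "another.txt"),
               class = "dtoolr_state_error")
  expect_error(freeze(proto), class = "dtoolr_state_error")

  # relpath hygiene
  proto2 <- create_proto_dataset("adder2", base)
  expect_error(add_item(proto2, f, "/abs.txt"),
               class = "dtoolr_validation_error")
  expect_error(add_item(proto2, f, "a/../b.txt"),
               class = "dtoolr_validation_error")
  expect_error(add_item(proto2, file.path(tempdir(), "nope"), "x.txt"),
               class = "dtoolr_io_error")
})

test_that("freeze computes a manifest whose keys are the item identifiers", {
  local_dt_sandbox()
  base <- local_base_uri("file")
  proto <- create_proto_dataset("frozen2", base)
  add_item(proto, local_content_file("aa"), "one.txt")
  add_item(proto, local_content_file("bbbb"), "two.txt")
  ds <- freeze(proto)

  expect_identical(ds$admin$state, "frozen")
  expect_true(is.numeric(as.numeric(ds$admin$frozen_at)))
  expect_setequal(names(ds$manifest$items),
                  c(generate_identifier("one.txt"),
                    generate_identifier("two.txt")))
  for (id in names(ds$manifest$items)) {
    it <- ds$manifest$items[[id]]
    expect_identical(generate_identifier(it$relpath), id)
    expect_identical(it$hash,
                     hash_file_content(fetch_item(ds, id))$digest)
  }
  # additivity: 2 + 4 bytes
  expect_identical(summarize_dataset(ds)$total_size_in_bytes, 6)
})

test_that("freezing an empty proto dataset gives a valid empty dataset", {
  local_dt_sandbox()
  ds <- freeze(create_proto_dataset("empty-ds", local_base_uri("file")))
  expect_identical(list_identifiers(ds), character(0))
  s <- summarize_dataset(ds)
  expect_identical(s$number_of_items, 0L)
  expect_identical(format_size(s$total_size_in_bytes), "0.0B")
  expect_true(verify(ds, full = TRUE)$ok)
})

test_that("freeze trusts storage, not the add_item call history", {
  local_dt_sandbox()
  base <- local_base_uri("file")
  proto <- create_proto_dataset("sneaky", base)
  add_item(proto, local_content_file("via api"), "api.txt")
  # a file placed in the data area without add_item is still manifested
  writeLines("by hand", file.path(base, "sneaky", "data", "manual.txt"))
  ds <- freeze(proto)
  expect_setequal(
    vapply(ds$manifest$items, function(it) it$relpath, character(1)),
    c("api.txt", "manual.txt")
  )
})

test_that("loading distinguishes missing, proto and frozen datasets", {
  local_dt_sandbox()
  base <- local_base_uri("file")
  expect_error(load_dataset(file.path(base, "absent")),
               class = "dtoolr_not_found_error")

  proto <- create_proto_dataset("still-proto", base)
  err <- tryCatch(load_dataset(dataset_uri(proto)), error = identity)
  expect_s3_class(err, "dtoolr_proto_error")
  expect_match(conditionMessage(err), "proto")

  ds <- freeze(proto)
  expect_error(load_proto_dataset(dataset_uri(ds)),
               class = "dtoolr_state_error")
})

test_that("identifiers list in ascending lexicographic order", {
  local_dt_sandbox()
  uri <- make_fixture_dataset(paper_reads_fixture_spec(),
                              local_base_uri("file"))
  ds <- load_dataset(uri)
  expect_identical(
    list_identifiers(ds),
    c("8bda245a8cd526673aab775f90206c8b67d196af",
      "9760280dc6313d3bb598fa03c5931a7f037d7ffc")
  )
  # permutation of manifest keys
  expect_setequal(list_identifiers(ds), names(ds$manifest$items))
})

test_that("fetch returns a readable path whose content matches the manifest", {
  local_dt_sandbox()
  for (scheme in c("file", "mock")) {
    uri <- make_paired_reads_dataset(local_base_uri(scheme))
    ds <- load_dataset(uri)
    for (id in list_identifiers(ds)) {
      path <- fetch_item(ds, id)
      expect_true(file.exists(path))
      expect_true(startsWith(path, "/"))
      expect_identical(hash_file_content(path)$digest,
                       item_properties(ds, id)$hash)
      # idempotent: second fetch returns the same path
      expect_identical(fetch_item(ds, id), path)
    }
    err <- tryCatch(fetch_item(ds, strrep("0", 40)), error = identity)
    expect_s3_class(err, "dtoolr_not_found_error")
    expect_match(conditionMessage(err), ds$uri$uri, fixed = TRUE)
  }
})

test_that("verify reports missing, unknown, altered-size and altered-hash items", {
  local_dt_sandbox()
  base <- local_base_uri("file")
  uri <- make_fixture_dataset(
    fixture_spec("verifiable",
                 items = list(
                   fixture_item("U00096.3.fasta", content = ">x\nACGT\n"),
                   fixture_item("notes.txt", content = "fine\n")
                 )),
    base
  )
  ds <- load_dataset(uri)
  expect_true(verify(ds)$ok)
  expect_true(verify(ds, full = TRUE)$ok)

  # remove an item -> missing, with identifier and relpath
  fasta <- file.path(base, "verifiable", "data", "U00096.3.fasta")
  file.rename(fasta, file.path(base, "U00096.3.fasta"))
  rep <- verify(ds)
  expect_false(rep$ok)
  expect_identical(rep$missing$identifier,
                   "b445ff5a1e468ab48628a00a944cac2e007fb9bc")
  expect_identical(rep$missing$relpath, "U00096.3.fasta")
  file.rename(file.path(base, "U00096.3.fasta"), fasta)

  # a stray file in the data area -> unknown
  writeLines("stray", file.path(base, "verifiable", "data", "stray.txt"))
  rep <- verify(ds)
  expect_identical(rep$unknown, generate_identifier("stray.txt"))
  unlink(file.path(base, "verifiable", "data", "stray.txt"))

  # size-preserving corruption: default mode blind, full mode catches it
  flip_byte(fasta, 4)
  expect_true(verify(ds)$ok)
  full <- verify(ds, full = TRUE)
  expect_false(full$ok)
  expect_identical(full$altered_hash$relpath, "U00096.3.fasta")

  # size change is caught in default mode
  writeLines("now much longer than before", fasta)
  rep <- verify(ds)
  expect_false(rep$ok)
  expect_identical(rep$altered_size$relpath, "U00096.3.fasta")
})

test_that("summaries aggregate the manifest and format like the transcripts", {
  local_dt_sandbox()
  uri <- make_fixture_dataset(paper_reads_fixture_spec(),
                              local_base_uri("file"))
  s <- summarize_dataset(load_dataset(uri))
  expect_identical(s$number_of_items, 2L)
  expect_identical(s$total_size_in_bytes, 3858445043)
  expect_identical(format_size(s$total_size_in_bytes), "3.6GiB")

  kib <- make_fixture_dataset(
    fixture_spec("one-kib",
                 items = list(fixture_item("k.bin",
                                           content = as.raw(rep(0, 1024))))),
    local_base_uri("file")
  )
  s2 <- summarize_dataset(load_dataset(kib))
  expect_identical(format_size(s2$total_size_in_bytes), "1.0KiB")
})
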