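# Inventory reports and fixture generation.

test_that("all three inventory formats carry identical rows", {
  local_dt_sandbox()
  base <- local_base_uri("file")
  make_fixture_dataset(paper_reads_fixture_spec(), base)
  make_paired_reads_dataset(base, name = "reads-a")
  make_paired_reads_dataset(base, name = "reads-b")

  csv <- read.csv(text = build_inventory(base, "csv"),
                  stringsAsFactors = FALSE)
  expect_identical(nrow(csv), 3L)
  expect_identical(csv$name, sort(csv$name))
  expect_identical(
    names(csv),
    c("name", "uuid", "creator_username", "number_of_items", "size",
      "frozen_at", "uri")
  )
  paper_row <- csv[csv$name == "Escherichia-coli-reads-ERR022075", ]
  expect_identical(paper_row$size, "3.6GiB")
  expect_identical(paper_row$number_of_items, 2L)
  expect_identical(paper_row$frozen_at, "2018-09-26")

  js <- jsonlite::fromJSON(build_inventory(base, "json"))
  expect_identical(js$name, csv$name)
  expect_identical(js$uuid, csv$uuid)
  expect_identical(js$size, csv$size)

  html <- build_inventory(base, "html")
  expect_match(html, "^<!DOCTYPE html>")
  expect_false(grepl("<script", html))
  for (i in seq_len(nrow(csv))) {
    expect_match(html, paste0("<td>", csv$name[i], "</td>"), fixed = TRUE)
    expect_match(html, paste0("<td>", csv$uuid[i], "</td>"), fixed = TRUE)
  }
})

test_that("an empty base yields a valid zero-row report", {
  local_dt_sandbox()
  base <- local_base_uri("file")
  csv <- read.csv(text = build_inventory(base, "csv"))
  expect_identical(nrow(csv), 0L)
  expect_identical(jsonlite::fromJSON(build_inventory(base, "json")),
                   list())
  expect_match(build_inventory(base, "html"), "<tbody>")
})

test_that("inventory row count matches the dataset listing", {
  local_dt_sandbox()
  base <- local_base_uri("file")
  make_paired_reads_dataset(base, name = "only-one")
  create_proto_dataset("not-counted-proto", base)
  csv <- read.csv(text = build_inventory(base, "csv"))
  listed <- list_datasets(base)
  expect_identical(nrow(csv), sum(listed$state == "frozen"))
})

test_that("inventory generation leaves datasets byte-identical", {
  local_dt_sandbox()
  base <- local_base_uri("file")
  make_paired_reads_dataset(base, name = "untouched")
  snapshot <- function() {
    files <- sort(list.files(base, recursive = TRUE, all.files = TRUE,
                             full.names = TRUE))
    vapply(files, function(f) digest::digest(file = f, algo = "md5"),
           character(1))
  }
  before <- snapshot()
  build_inventory(base, "html")
  build_inventory(base, "csv")
  build_inventory(base, "json")
  expect_identical(snapshot(), before)
})

test_that("fixture generation is deterministic given the seed", {
  local_dt_sandbox()
  spec <- fixture_spec("det-check",
                       items = synthetic_paired_fastq_items(seed = 42),
                       seed = 42)
  uri_a <- make_fixture_dataset(spec, local_base_uri("file"))
  uri_b <- make_fixture_dataset(spec, local_base_uri("file"))
  manifest <- function(uri) {
    p <- file.path(parse_uri(uri)$location, ".dtool", "manifest.json")
    readChar(p, file.size(p), useBytes = TRUE)
  }
  # identical manifests (content, sizes, hashes, timestamps); distinct UUIDs
  expect_identical(manifest(uri_a), manifest(uri_b))
  expect_false(load_dataset(uri_a)$admin$uuid ==
                 load_dataset(uri_b)$admin$uuid)
})

test_that("manifest-level and content fixtures agree where no bytes are read", {
  local_dt_sandbox()
  base <- local_base_uri("file")
  content_uri <- make_paired_reads_dataset(base, name = "with-bytes")
  declared <- fixture_spec(
    "without-bytes",
    items = list(
      fixture_item("ERR022075_1.fastq.gz", size = 123,
                   utc_timestamp = 1537805358),
      fixture_item("ERR022075_2.fastq.gz", size = 456,
                   utc_timestamp = 1537805410)
    )
  )
  declared_uri <- make_fixture_dataset(declared, base)
  a <- load_dataset(content_uri)
  b <- load_dataset(declared_uri)
  # identifiers and relpaths agree; summaries both work without reading bytes
  expect_identical(list_identifiers(a), list_identifiers(b))
  expect_identical(summarize_dataset(b)$total_size_in_bytes, 579)
  expect_identical(summarize_dataset(b)$number_of_items, 2L)
})
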