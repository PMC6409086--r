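# Shared fixtures and helpers. All datasets are generated in temporary
# directories; nothing touches the user's real configuration or cache.

# Isolate configuration, cache and creator name for the calling test.
local_dt_sandbox <- function(creator = "testuser",
                             env = parent.frame()) {
  withr::local_envvar(
    c(DTOOLR_CONFIG = file.path(withr::local_tempdir(.local_envir = env),
                                "no-config.json"),
      DTOOLR_CACHE_ROOT = withr::local_tempdir(.local_envir = env),
      DTOOLR_CREATOR_USERNAME = creator),
    .local_envir = env
  )
}

# Fresh base location for a given broker scheme.
local_base_uri <- function(scheme = "file", env = parent.frame()) {
  dir <- withr::local_tempdir(.local_envir = env)
  switch(scheme,
         file = dir,
         mock = paste0("mock://", dir),
         stop("unknown scheme ", scheme))
}

# Write `content` (character or raw) to a temp file, optionally pinning its
# modification time (UTC epoch seconds).
local_content_file <- function(content, mtime = NULL, env = parent.frame()) {
  path <- withr::local_tempfile(.local_envir = env)
  if (is.raw(content)) {
    writeBin(content, path)
  } else {
    writeBin(charToRaw(content), path)
  }
  if (!is.null(mtime)) {
    Sys.setFileTime(path, as.POSIXct(mtime, origin = "1970-01-01", tz = "UTC"))
  }
  path
}

# The printed two-read *E. coli* manifest, as a manifest-level fixture
# (declared multi-GiB sizes, no real bytes). Administrative values pinned so
# transcript-fidelity tests can compare byte for byte.
PAPER_READS_UUID <- "faa44606-cb86-4877-b9ea-643a3777e021"
PAPER_READS_FROZEN_AT <- as.numeric(as.POSIXct("2018-09-26 12:00:00",
                                               tz = "UTC"))

paper_reads_fixture_spec <- function() {
  fixture_spec(
    name = "Escherichia-coli-reads-ERR022075",
    items = list(
      fixture_item("ERR022075_2.fastq.gz", size = 1982742623,
                   hash = "78608288625e084d68b4b5e8c1725933",
                   utc_timestamp = 1537805410),
      fixture_item("ERR022075_1.fastq.gz", size = 1875702420,
                   hash = "4766e60e72da987e4c54e47fee5653a4",
                   utc_timestamp = 1537805358)
    ),
    readme = paste0("---\n",
                    "description: Whole Genome Sequencing of Escherichia ",
                    "coli str. K-12 MG1655\n"),
    uuid = PAPER_READS_UUID,
    creator_username = "olssont",
    frozen_at = PAPER_READS_FROZEN_AT
  )
}

# Content-backed paired-read dataset (small synthetic gzipped FASTQ).
make_paired_reads_dataset <- function(base_uri, name = "synthetic-reads",
                                      seed = 1L) {
  make_fixture_dataset(
    fixture_spec(name = name,
                 items = synthetic_paired_fastq_items(seed = seed),
                 readme = "---\ndescription: synthetic paired reads\n",
                 seed = seed),
    base_uri
  )
}

# Random content-backed dataset for property-style tests.
make_random_dataset <- function(base_uri, n_items, seed,
                                name = sprintf("random-ds-%d", seed)) {
  set.seed(seed)
  items <- lapply(seq_len(n_items), function(i) {
    n <- 19L + sample.int(200, 1)
    fixture_item(sprintf("dir%d/item-%02d.bin", i %% 3, i),
                 content = as.raw(sample.int(256, n, replace = TRUE) - 1L),
                 utc_timestamp = 1537800000 + i)
  })
  make_fixture_dataset(
    fixture_spec(name = name, items = items, readme = "---\nrandom: true\n",
                 seed = seed),
    base_uri
  )
}

# Property suite: create -> add n items -> freeze -> load -> fetch/verify,
# random fixtures, fixed seed. Runs unchanged against either broker scheme.
lifecycle_roundtrip_suite <- function(scheme) {
  local_dt_sandbox()
  set.seed(20240901)
  for (rep in 1:4) {
    n <- sample.int(20, 1)
    base <- local_base_uri(scheme)
    seed <- sample.int(1e6, 1)
    uri <- make_random_dataset(base, n, seed)
    ds <- load_dataset(uri)

    ids <- list_identifiers(ds)
    expect_identical(length(ids), as.integer(n))
    expect_identical(ids, sort(ids))
    expect_true(verify(ds, full = TRUE)$ok)

    # every sampled item fetches to bytes matching its manifest hash
    for (id in sample(ids, min(3, n))) {
      expect_identical(hash_file_content(fetch_item(ds, id))$digest,
                       item_properties(ds, id)$hash)
    }
  }
}

# Property suite: single-byte corruption (sizes preserved) is always caught
# in full mode; exhaustive over items, sampled over byte positions.
corruption_detection_suite <- function(scheme) {
  local_dt_sandbox()
  base <- local_base_uri(scheme)
  uri <- make_random_dataset(base, n_items = 4, seed = 77)
  ds <- load_dataset(uri)
  set.seed(99)
  for (id in list_identifiers(ds)) {
    it <- item_properties(ds, id)
    path <- stored_item_file(uri, id, it$relpath)
    original <- readBin(path, "raw", file.size(path))
    for (offset in sample.int(length(original), 2) - 1L) {
      flip_byte(path, offset)
      expect_false(verify(ds, full = TRUE)$ok,
                   info = sprintf("%s offset %d on %s", id, offset, scheme))
      writeBin(original, path)
    }
    expect_true(verify(ds, full = TRUE)$ok)
  }
}

# Run a CLI invocation in-process, capturing stdout, stderr and exit code.
run_cli <- function(args) {
  code <- NULL
  err <- character(0)
  out <- withCallingHandlers(
    capture.output(
      err <- capture.output(code <- cli_dispatch(args), type = "message"),
      type = "output"
    )
  )
  list(code = code, out = out, err = err)
}

# Independent SHA-1 oracle (Python hashlib), one subprocess for all inputs.
python_sha1_oracle <- function(strings) {
  infile <- tempfile()
  writeLines(strings, infile, useBytes = TRUE)
  script <- paste(
    "import hashlib, sys",
    "with open(sys.argv[1], 'rb') as fh:",
    "    for line in fh.read().split(b'\\n')[:-1]:",
    "        print(hashlib.sha1(line).hexdigest())",
    sep = "\n")
  out <- system2("python", c("-c", shQuote(script), shQuote(infile)),
                 stdout = TRUE)
  unlink(infile)
  out
}

# Flip one byte of a file in place (sizes preserved).
flip_byte <- function(path, offset) {
  con <- file(path, open = "r+b")
  on.exit(close(con))
  seek(con, where = offset, rw = "read")
  b <- readBin(con, "raw", n = 1)
  seek(con, where = offset, rw = "write")
  writeBin(xor(b, as.raw(0xff)), con)
}

# Path of the file that actually stores an item's bytes, for corruption
# tests (dataset-layout aware for both brokers).
stored_item_file <- function(ds_uri, identifier, relpath) {
  uri <- parse_uri(ds_uri)
  if (uri$scheme == "file") {
    file.path(uri$location, "data", relpath)
  } else {
    file.path(uri$location, "data", identifier)
  }
}
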