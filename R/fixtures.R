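# Synthetic fixture datasets.
#
# Every test and example in this package runs against datasets generated
# here: small paired FASTQ-like gzipped items, a reference-FASTA-like item,
# or "manifest-level" fixtures that state arbitrary item sizes in the
# manifest without materializing the bytes (so multi-GiB datasets can be
# summarized without multi-GiB files). Generation is deterministic given the
# spec's seed; item timestamps are pinned so repeated generation yields
# byte-identical manifests (UUIDs excepted, unless pinned explicitly).

#' Describe a fixture item
#'
#' Either `content` (real bytes; the item is stored and fetchable) or `size`
#' (declared size for a manifest-level fixture; the item is not fetchable)
#' must be given.
#'
#' @param relpath Relative path of the item.
#' @param content Item content as a character string or raw vector, or `NULL`.
#' @param size Declared size in bytes for manifest-level items.
#' @param hash Declared content hash for manifest-level items; defaults to a
#'   synthetic digest derived from the relpath.
#' @param utc_timestamp Item timestamp (UTC epoch seconds).
#' @return A `fixture_item` list.
#' @export
fixture_item <- function(relpath, content = NULL, size = NULL, hash = NULL,
                         utc_timestamp = 1537805410) {
  if (is.null(content) && is.null(size)) {
    stop_validation("fixture item needs either content or a declared size")
  }
  structure(
    list(relpath = relpath, content = content, size = size, hash = hash,
         utc_timestamp = utc_timestamp),
    class = "fixture_item"
  )
}

#' Describe a fixture dataset
#'
#' @param name Dataset name.
#' @param items List of [fixture_item()]s.
#' @param readme Descriptive-metadata text.
#' @param seed Integer seed controlling any generated content.
#' @param uuid,creator_username,frozen_at Optional pinned administrative
#'   values (used where byte-exact transcripts are needed); defaults are a
#'   fresh UUID, the configured username and the generation time.
#' @return A `fixture_spec` list.
#' @export
fixture_spec <- function(name, items, readme = "", seed = 1L, uuid = NULL,
                         creator_username = NULL, frozen_at = NULL) {
  structure(
    list(name = name, items = items, readme = readme, seed = as.integer(seed),
         uuid = uuid, creator_username = creator_username,
         frozen_at = frozen_at),
    class = "fixture_spec"
  )
}

with_preserved_rng <- function(expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(suppressWarnings(
      rm(".Random.seed", envir = globalenv())
    ), add = TRUE)
  }
  expr
}

#' Generate synthetic paired sequencing reads as gzipped FASTQ items
#'
#' Emulates a paired-end short-read dataset: two items named
#' `<prefix>_1.fastq.gz` and `<prefix>_2.fastq.gz` with matching read names
#' ending `/1` and `/2`. Content is deterministic given the seed (the gzip
#' stream carries no timestamp), and small: this stands in for raw sequencing
#' data at desk scale.
#'
#' @param prefix Run prefix used in file and read names.
#' @param n_reads Reads per file.
#' @param read_length Bases per read.
#' @param seed Integer seed.
#' @param timestamps Length-2 vector of item timestamps (read 1, read 2).
#' @return List of two [fixture_item()]s.
#' @export
synthetic_paired_fastq_items <- function(prefix = "ERR022075", n_reads = 5L,
                                         read_length = 36L, seed = 1L,
                                         timestamps = c(1537805358,
                                                        1537805410)) {
  make_fastq <- function(read_no) {
    with_preserved_rng({
      # same seed for both mates so the sequences pair up deterministically
      set.seed(seed)
      lines <- character(0)
      for (i in seq_len(n_reads)) {
        bases <- paste(sample(c("A", "C", "G", "T"), read_length,
                              replace = TRUE), collapse = "")
        qual <- paste(sample(strsplit("!#%+5>ABCDEFGHI", "")[[1]],
                             read_length, replace = TRUE), collapse = "")
        lines <- c(lines,
                   sprintf("@%s.%d EAS600_70:5:1:%d:%d/%d", prefix, i,
                           1000 + i, 900 + i, read_no),
                   bases, "+", qual)
      }
      paste0(paste(lines, collapse = "\n"), "\n")
    })
  }
  list(
    fixture_item(sprintf("%s_1.fastq.gz", prefix),
                 content = gzip_bytes(make_fastq(1L)),
                 utc_timestamp = timestamps[1]),
    fixture_item(sprintf("%s_2.fastq.gz", prefix),
                 content = gzip_bytes(make_fastq(2L)),
                 utc_timestamp = timestamps[2])
  )
}

#' Generate a synthetic reference-genome FASTA item
#'
#' @param relpath Relative path, defaulting to an *E. coli*-style accession.
#' @param n_bases Sequence length.
#' @param seed Integer seed.
#' @param utc_timestamp Item timestamp.
#' @return A [fixture_item()].
#' @export
synthetic_fasta_item <- function(relpath = "U00096.3.fasta", n_bases = 280L,
                                 seed = 1L, utc_timestamp = 1537805410) {
  content <- with_preserved_rng({
    set.seed(seed)
    seq <- paste(sample(c("A", "C", "G", "T"), n_bases, replace = TRUE),
                 collapse = "")
    chunks <- substring(seq, seq(1, n_bases, 70),
                        pmin(seq(1, n_bases, 70) + 69, n_bases))
    paste0(">", sub("\\.fasta$", "", basename(relpath)),
           " synthetic reference sequence\n",
           paste(chunks, collapse = "\n"), "\n")
  })
  fixture_item(relpath, content = content, utc_timestamp = utc_timestamp)
}

# deterministic gzip container: gzfile() zeroes the header mtime and stores
# no file name, so identical text yields identical bytes
gzip_bytes <- function(text) {
  tmp <- tempfile(fileext = ".gz")
  on.exit(unlink(tmp))
  con <- gzfile(tmp, "wb")
  writeBin(charToRaw(enc2utf8(text)), con)
  close(con)
  readBin(tmp, "raw", file.size(tmp))
}

item_raw_content <- function(content) {
  if (is.raw(content)) content else charToRaw(enc2utf8(content))
}

#' Materialize a fixture dataset under a base URI
#'
#' Content fixtures go through the normal lifecycle (create, add items,
#' freeze), so they are full, fetchable, verifiable datasets. Manifest-level
#' fixtures (all items carrying declared sizes instead of content) get their
#' manifest written directly with the stated sizes, hashes and timestamps;
#' they support every operation that does not read item bytes (name, uuid,
#' summary, ls, identifiers) without materializing large files.
#'
#' @param spec A [fixture_spec()].
#' @param base_uri Base location to create the dataset under.
#' @return The dataset's URI as text.
#' @export
make_fixture_dataset <- function(spec, base_uri) {
  stopifnot(inherits(spec, "fixture_spec"))
  has_content <- vapply(spec$items, function(it) !is.null(it$content),
                        logical(1))
  if (any(has_content) && !all(has_content)) {
    stop_validation(
      "fixture items must be all content-backed or all declared-size")
  }
  creator <- if (is.null(spec$creator_username)) {
    dt_creator_username()
  } else {
    spec$creator_username
  }
  proto <- create_proto_dataset(spec$name, base_uri,
                                creator_username = creator)
  write_readme(proto, spec$readme)
  if (all(has_content) && length(spec$items) > 0L) {
    for (it in spec$items) {
      tmp <- tempfile()
      on.exit(unlink(tmp), add = TRUE)
      writeBin(item_raw_content(it$content), tmp)
      Sys.setFileTime(tmp, as.POSIXct(it$utc_timestamp,
                                      origin = "1970-01-01", tz = "UTC"))
      add_item(proto, tmp, it$relpath)
      unlink(tmp)
    }
    ds <- freeze(proto)
  } else {
    # manifest-level fixture: write the manifest directly from declared values
    items <- list()
    for (it in spec$items) {
      id <- generate_identifier(it$relpath)
      hash <- if (is.null(it$hash)) {
        # synthetic digest: stands in for a real content hash
        digest::digest(charToRaw(enc2utf8(it$relpath)), algo = "md5",
                       serialize = FALSE)
      } else {
        it$hash
      }
      items[[id]] <- list(hash = hash, relpath = it$relpath,
                          size_in_bytes = as.numeric(it$size),
                          utc_timestamp = as.numeric(it$utc_timestamp))
    }
    manifest <- list(dtoolcore_version = FORMAT_VERSION,
                     hash_function = DEFAULT_HASH_LABEL, items = items)
    broker_put_text(proto$broker, "manifest", manifest_to_json(manifest))
    admin <- read_admin(proto$broker)
    admin$state <- "frozen"
    admin$frozen_at <- as.numeric(Sys.time())
    write_admin(proto$broker, admin)
    ds <- load_dataset(proto$uri)
  }
  # pin administrative values where a byte-exact transcript needs them
  if (!is.null(spec$uuid) || !is.null(spec$frozen_at)) {
    admin <- read_admin(ds$broker)
    if (!is.null(spec$uuid)) {
      admin$uuid <- tolower(spec$uuid)
    }
    if (!is.null(spec$frozen_at)) {
      admin$frozen_at <- as.numeric(spec$frozen_at)
    }
    write_admin(ds$broker, admin)
  }
  dataset_uri(ds)
}
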