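# Item identifiers, content hashing and human-readable sizes.
#
# These are the numeric heart of the dataset format: identifiers address items
# independently of storage medium, content hashes underpin fixity checking and
# the size formatter produces the figures shown by `summary` and `ls`.

# Registry of content-hash algorithms, keyed by the label recorded in the
# manifest's "hash_function" field. The label is authoritative when reading a
# manifest, so verification always uses the algorithm the dataset was frozen
# with, whatever the current default.
.hash_registry <- new.env(parent = emptyenv())

#' Register a content-hash algorithm
#'
#' @param label Manifest label for the algorithm, e.g. `"md5sum_hexdigest"`.
#' @param file_fun Function taking a file path and returning the lowercase hex
#'   digest of the file's bytes. Implementations must hash in fixed-size
#'   chunks so memory use is independent of file size.
#' @export
register_hash_algorithm <- function(label, file_fun) {
  stopifnot(is.character(label), length(label) == 1L, is.function(file_fun))
  assign(label, file_fun, envir = .hash_registry)
  invisible(label)
}

registered_hash_algorithms <- function() {
  sort(ls(.hash_registry))
}

# Default manifest hash function: MD5, recorded as "md5sum_hexdigest".
DEFAULT_HASH_LABEL <- "md5sum_hexdigest"

register_default_hash_algorithms <- function() {
  # digest(file=) streams in fixed-size chunks (constant memory).
  register_hash_algorithm("md5sum_hexdigest", function(path) {
    digest::digest(file = path, algo = "md5")
  })
  register_hash_algorithm("sha1sum_hexdigest", function(path) {
    digest::digest(file = path, algo = "sha1")
  })
  register_hash_algorithm("sha256sum_hexdigest", function(path) {
    digest::digest(file = path, algo = "sha256")
  })
}

#' Compute the identifier of an item from its relative path
#'
#' Item identifiers are the SHA-1 hex digest of the UTF-8 encoding of the
#' item's relative path (forward-slash separated). They are pure functions of
#' the relpath: the same relpath yields the same 40-character identifier on
#' every storage backend, which is what lets processing scripts address items
#' without caring where the dataset lives.
#'
#' @param relpath Relative path of the item within the dataset, e.g.
#'   `"ERR022075_1.fastq.gz"` or `"subdir/reads.fq"`.
#' @return A 40-character lowercase hexadecimal string.
#' @examples
#' generate_identifier("ERR022075_2.fastq.gz")
#' @export
generate_identifier <- function(relpath) {
  if (!is.character(relpath) || length(relpath) != 1L || is.na(relpath)) {
    stop_validation("relpath must be a single character string")
  }
  digest::digest(charToRaw(enc2utf8(relpath)), algo = "sha1", serialize = FALSE)
}

#' Hash the content of a file
#'
#' Streams the file's bytes through the algorithm registered under `algorithm`
#' (memory use is independent of file size).
#'
#' @param path Path of an existing, readable file.
#' @param algorithm Manifest label of a registered algorithm; the default is
#'   MD5 under the label `"md5sum_hexdigest"`.
#' @return A list with elements `algorithm_name` and `digest` (lowercase hex).
#' @export
hash_file_content <- function(path, algorithm = DEFAULT_HASH_LABEL) {
  if (!exists(algorithm, envir = .hash_registry, inherits = FALSE)) {
    stop_config(sprintf(
      "unknown hash algorithm '%s' (registered: %s)",
      algorithm, paste(registered_hash_algorithms(), collapse = ", ")
    ))
  }
  if (!file.exists(path) || dir.exists(path)) {
    stop_io(sprintf("cannot read file '%s'", path))
  }
  fun <- get(algorithm, envir = .hash_registry)
  list(algorithm_name = algorithm, digest = fun(path))
}

# Binary-prefix units; 1 KiB = 1024 B.
.size_units <- c("B", "KiB", "MiB", "GiB", "TiB")

#' Format a byte count with binary prefixes
#'
#' Picks the largest unit (B, KiB, MiB, GiB, TiB) in which the value is at
#' least 1 (bytes for anything under 1024) and prints it with one decimal
#' place, rounding half up. Note this is rounding, not truncation:
#' 3,858,445,043 bytes is about 3.593 GiB and formats as `"3.6GiB"`.
#'
#' @param n_bytes Non-negative number of bytes.
#' @return Text such as `"1.8GiB"`; no space between number and unit.
#' @examples
#' format_size(1982742623)
#' format_size(1024)
#' @export
format_size <- function(n_bytes) {
  if (!is.numeric(n_bytes) || length(n_bytes) != 1L || is.na(n_bytes) ||
      n_bytes < 0) {
    stop_validation("n_bytes must be a single non-negative number")
  }
  n_bytes <- as.numeric(n_bytes)
  idx <- 1L
  while (idx < length(.size_units) && n_bytes / 1024^idx >= 1) {
    idx <- idx + 1L
  }
  value <- n_bytes / 1024^(idx - 1L)
  # round half up on the first decimal (base round() is half-to-even)
  rounded <- floor(value * 10 + 0.5) / 10
  sprintf("%.1f%s", rounded, .size_units[idx])
}
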