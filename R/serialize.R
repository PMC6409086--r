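# JSON serialization of the structural and administrative metadata.
#
# The manifest layout is a format contract: top-level keys "dtoolcore_version",
# "hash_function", "items"; keys sorted lexicographically; 2-space indent;
# timestamps written as decimal numbers (e.g. 1537805410.0). A bespoke writer
# is used because generic JSON emitters will not print a whole-second
# timestamp with its trailing ".0".

FORMAT_VERSION <- "3.7.0"

json_escape <- function(s) {
  s <- gsub("\\", "\\\\", s, fixed = TRUE)
  s <- gsub("\"", "\\\"", s, fixed = TRUE)
  s <- gsub("\n", "\\n", s, fixed = TRUE)
  s <- gsub("\r", "\\r", s, fixed = TRUE)
  s <- gsub("\t", "\\t", s, fixed = TRUE)
  s
}

json_str <- function(s) paste0("\"", json_escape(s), "\"")

# byte counts: exact integers, never scientific notation
json_int <- function(n) sprintf("%.0f", n)

# timestamps: at least one decimal place, up to microseconds, no trailing zeros
json_timestamp <- function(ts) {
  s <- sprintf("%.6f", ts)
  s <- sub("0+$", "", s)
  if (endsWith(s, ".")) s <- paste0(s, "0")
  s
}

manifest_to_json <- function(manifest) {
  ids <- sort(names(manifest$items))
  item_blocks <- vapply(ids, function(id) {
    it <- manifest$items[[id]]
    paste0(
      "    ", json_str(id), ": {\n",
      "      \"hash\": ", json_str(it$hash), ",\n",
      "      \"relpath\": ", json_str(it$relpath), ",\n",
      "      \"size_in_bytes\": ", json_int(it$size_in_bytes), ",\n",
      "      \"utc_timestamp\": ", json_timestamp(it$utc_timestamp), "\n",
      "    }"
    )
  }, character(1))
  items_json <- if (length(item_blocks) == 0L) {
    "{}"
  } else {
    paste0("{\n", paste(item_blocks, collapse = ",\n"), "\n  }")
  }
  paste0(
    "{\n",
    "  \"dtoolcore_version\": ", json_str(manifest$dtoolcore_version), ",\n",
    "  \"hash_function\": ", json_str(manifest$hash_function), ",\n",
    "  \"items\": ", items_json, "\n",
    "}\n"
  )
}

manifest_from_json <- function(text) {
  parsed <- jsonlite::fromJSON(text, simplifyVector = FALSE)
  items <- lapply(parsed$items, function(it) {
    list(
      hash = as.character(it$hash),
      relpath = as.character(it$relpath),
      size_in_bytes = as.numeric(it$size_in_bytes),
      utc_timestamp = as.numeric(it$utc_timestamp)
    )
  })
  list(
    dtoolcore_version = as.character(parsed$dtoolcore_version),
    hash_function = as.character(parsed$hash_function),
    items = items
  )
}

admin_to_json <- function(admin) {
  keys <- sort(names(admin))
  fields <- vapply(keys, function(k) {
    v <- admin[[k]]
    val <- if (is.numeric(v)) json_timestamp(v) else json_str(as.character(v))
    paste0("  ", json_str(k), ": ", val)
  }, character(1))
  paste0("{\n", paste(fields, collapse = ",\n"), "\n}\n")
}

admin_from_json <- function(text) {
  jsonlite::fromJSON(text, simplifyVector = TRUE)
}

overlay_to_json <- function(mapping) {
  ids <- sort(names(mapping))
  if (length(ids) == 0L) {
    return("{}")
  }
  fields <- vapply(ids, function(id) {
    v <- mapping[[id]]
    val <- if (is.null(v)) {
      "null"
    } else if (is.logical(v)) {
      if (v) "true" else "false"
    } else if (is.numeric(v)) {
      # bare number; keep integers integral
      if (v == floor(v) && abs(v) < 2^53) json_int(v) else format(v, digits = 15)
    } else {
      json_str(as.character(v))
    }
    paste0("  ", json_str(id), ": ", val)
  }, character(1))
  paste0("{\n", paste(fields, collapse = ",\n"), "\n}\n")
}

overlay_from_json <- function(text) {
  jsonlite::fromJSON(text, simplifyVector = FALSE)
}
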