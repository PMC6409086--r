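# The dataset abstraction: proto-dataset lifecycle, freezing, manifests,
# verification and copying. Everything here is medium-independent; all
# storage access flows through the broker contract.
#
# A dataset starts life as a mutable *proto dataset* to which items can be
# added. Freezing computes the manifest (per item: relative path, size,
# content hash, timestamp), stamps the freeze time and makes the dataset
# immutable. The manifest is what later supports fixity checking: presence,
# size and (in full mode) content-hash comparison.

SAFE_NAME_RE <- "^[A-Za-z0-9._-]+$"

validate_dataset_name <- function(name) {
  if (!is.character(name) || length(name) != 1L || is.na(name) ||
      !grepl(SAFE_NAME_RE, name)) {
    stop_validation(sprintf(
      "invalid dataset name '%s': use only letters, digits, '.', '-' and '_'",
      as.character(name)[1]
    ))
  }
  name
}

validate_relpath <- function(relpath) {
  if (!is.character(relpath) || length(relpath) != 1L || is.na(relpath) ||
      !nzchar(relpath)) {
    stop_validation("relpath must be non-empty text")
  }
  if (startsWith(relpath, "/")) {
    stop_validation(sprintf("relpath must be relative, got '%s'", relpath))
  }
  segs <- strsplit(relpath, "/", fixed = TRUE)[[1]]
  if (any(segs %in% c("", ".", ".."))) {
    stop_validation(sprintf(
      "relpath must not contain empty, '.' or '..' segments: '%s'", relpath
    ))
  }
  relpath
}

iso_utc_date <- function(epoch) {
  format(as.POSIXct(epoch, origin = "1970-01-01", tz = "UTC"), "%Y-%m-%d")
}

read_admin <- function(broker) {
  admin_from_json(broker_get_text(broker, "admin"))
}

write_admin <- function(broker, admin) {
  broker_put_text(broker, "admin", admin_to_json(admin))
}

#' Create a proto dataset
#'
#' A proto dataset is a dataset under construction: items can be added to it
#' until it is finalized with [freeze()]. The dataset is assigned a fresh
#' UUID that stays with it for life, including across copies between storage
#' backends.
#'
#' @param name Dataset name; letters, digits, `"."`, `"-"`, `"_"` only.
#' @param base_uri Location under which the dataset is created (a directory
#'   for `file://`, a store for `mock://`). Defaults to the working directory.
#' @param creator_username Recorded in the administrative metadata; defaults
#'   to the configured or operating-system username.
#' @return A `dt_proto_dataset` handle.
#' @export
create_proto_dataset <- function(name, base_uri = ".",
                                 creator_username = dt_creator_username()) {
  validate_dataset_name(name)
  base <- as_dt_uri(base_uri)
  entry <- broker_entry(base$scheme)
  ds_uuid <- tolower(uuid::UUIDgenerate())
  uri <- entry$dataset_uri(base, name, ds_uuid)
  broker <- entry$new_broker(uri)
  broker_create_structure(broker)
  admin <- list(
    created_at = as.numeric(Sys.time()),
    creator_username = creator_username,
    format_version = FORMAT_VERSION,
    name = name,
    state = "proto",
    uuid = ds_uuid
  )
  write_admin(broker, admin)
  # empty descriptive metadata so `readme show` works from the start
  broker_put_text(broker, "readme", "")
  structure(list(uri = uri, broker = broker, admin = admin),
            class = "dt_proto_dataset")
}

#' Load a proto dataset from its URI
#'
#' @param uri Dataset URI (or local path).
#' @return A `dt_proto_dataset` handle.
#' @export
load_proto_dataset <- function(uri) {
  uri <- as_dt_uri(uri)
  broker <- broker_for(uri)
  if (!broker_exists(broker)) {
    stop_not_found(sprintf("no dataset found at %s", uri$uri))
  }
  admin <- read_admin(broker)
  if (!identical(admin$state, "proto")) {
    stop_state(sprintf(
      "dataset at %s is frozen; frozen datasets are immutable", uri$uri
    ))
  }
  structure(list(uri = uri, broker = broker, admin = admin),
            class = "dt_proto_dataset")
}

#' Load a frozen dataset from its URI
#'
#' The returned handle behaves identically whatever the storage backend.
#'
#' @param uri Dataset URI (or local path).
#' @return A `dt_dataset` handle exposing the administrative record, the
#'   manifest, the readme and any overlays.
#' @export
load_dataset <- function(uri) {
  uri <- as_dt_uri(uri)
  broker <- broker_for(uri)
  if (!broker_exists(broker)) {
    stop_not_found(sprintf("no dataset found at %s", uri$uri))
  }
  admin <- read_admin(broker)
  if (identical(admin$state, "proto")) {
    stop(dt_error(
      c("dtoolr_proto_error", "dtoolr_state_error"),
      sprintf(paste0(
        "dataset at %s is a proto dataset; use load_proto_dataset() / ",
        "add_item() / freeze() to finish constructing it"), uri$uri)
    ))
  }
  manifest <- manifest_from_json(broker_get_text(broker, "manifest"))
  structure(list(uri = uri, broker = broker, admin = admin,
                 manifest = manifest),
            class = "dt_dataset")
}

#' Add an item to a proto dataset
#'
#' Stores the file's bytes in the dataset's data area under `relpath`. Adding
#' a second item with the same relpath replaces the previous content (last
#' write wins); the identifier, being a pure function of the relpath, is
#' unchanged.
#'
#' @param proto A `dt_proto_dataset` handle.
#' @param source_path Readable local file to add.
#' @param relpath Relative path the item gets inside the dataset; defaults to
#'   the source file's name.
#' @return The item's identifier (invisibly returned by brokers, visibly
#'   here).
#' @export
add_item <- function(proto, source_path, relpath = basename(source_path)) {
  stopifnot(inherits(proto, "dt_proto_dataset"))
  admin <- read_admin(proto$broker)
  if (!identical(admin$state, "proto")) {
    stop_state(sprintf("cannot add items: dataset at %s is frozen",
                       proto$uri$uri))
  }
  if (!file.exists(source_path) || dir.exists(source_path)) {
    stop_io(sprintf("cannot read source file '%s'", source_path))
  }
  validate_relpath(relpath)
  broker_put_item(proto$broker, source_path, relpath)
  generate_identifier(relpath)
}

#' Freeze a proto dataset
#'
#' Finalization: the manifest is computed from the bytes actually in storage
#' (storage, not the add_item call history, is the source of truth), the
#' freeze time is stamped and the dataset becomes immutable.
#'
#' @param proto A `dt_proto_dataset` handle.
#' @param hash_algorithm Manifest label of the content-hash algorithm to use.
#' @return The frozen `dt_dataset` handle.
#' @export
freeze <- function(proto, hash_algorithm = DEFAULT_HASH_LABEL) {
  stopifnot(inherits(proto, "dt_proto_dataset"))
  admin <- read_admin(proto$broker)
  if (!identical(admin$state, "proto")) {
    stop_state(sprintf("dataset at %s is already frozen", proto$uri$uri))
  }
  stored <- broker_stored_items(proto$broker)
  if (anyNA(stored$relpath)) {
    stop_broker("storage holds items with no recorded relative path")
  }
  if (anyDuplicated(stored$relpath)) {
    stop_broker("storage holds items with duplicate relative paths")
  }
  items <- list()
  for (i in seq_len(nrow(stored))) {
    id <- stored$identifier[i]
    items[[id]] <- list(
      hash = broker_item_hash(proto$broker, id, stored$relpath[i],
                              hash_algorithm),
      relpath = stored$relpath[i],
      size_in_bytes = stored$size_in_bytes[i],
      utc_timestamp = stored$utc_timestamp[i]
    )
  }
  manifest <- list(dtoolcore_version = FORMAT_VERSION,
                   hash_function = hash_algorithm,
                   items = items)
  broker_put_text(proto$broker, "manifest", manifest_to_json(manifest))
  admin$state <- "frozen"
  admin$frozen_at <- as.numeric(Sys.time())
  write_admin(proto$broker, admin)
  load_dataset(proto$uri)
}

#' List the identifiers of a dataset's items
#'
#' @param dataset A `dt_dataset` handle.
#' @return Character vector of identifiers in ascending lexicographic order.
#' @export
list_identifiers <- function(dataset) {
  stopifnot(inherits(dataset, "dt_dataset"))
  sort(names(dataset$manifest$items))
}

manifest_item <- function(dataset, identifier) {
  it <- dataset$manifest$items[[identifier]]
  if (is.null(it)) {
    stop_not_found(sprintf("no item with identifier '%s' in dataset at %s",
                           identifier, dataset$uri$uri))
  }
  it
}

#' Properties of a single item
#'
#' @param dataset A `dt_dataset` handle.
#' @param identifier Item identifier.
#' @return List with `relpath`, `size_in_bytes`, `hash`, `utc_timestamp`.
#' @export
item_properties <- function(dataset, identifier) {
  manifest_item(dataset, identifier)
}

#' Fetch an item to a local path
#'
#' Returns an absolute path from which the item's content can be read. On a
#' plain-filesystem dataset this is the stored file itself; on an
#' object-store-like backend the item is first materialized into a local
#' cache (the second fetch reuses the cached copy).
#'
#' @param dataset A `dt_dataset` handle.
#' @param identifier Item identifier.
#' @return Absolute path of a readable local file.
#' @export
fetch_item <- function(dataset, identifier) {
  it <- manifest_item(dataset, identifier)
  broker_item_path(dataset$broker, identifier, it$relpath)
}

#' Verify the integrity of a dataset
#'
#' Fixity checking against the manifest. The default mode checks that every
#' expected item is present with the expected size; `full = TRUE` additionally
#' recomputes content hashes (slower, but catches same-size corruption).
#' Items found in storage that the manifest does not know about are reported
#' as unknown. Discrepancies are report content, never errors.
#'
#' @param dataset A `dt_dataset` handle.
#' @param full Recompute content hashes as well.
#' @return A `dt_verify_report` with fields `ok`, `missing`, `unknown`,
#'   `altered_size`, `altered_hash`.
#' @export
verify <- function(dataset, full = FALSE) {
  stopifnot(inherits(dataset, "dt_dataset"))
  manifest <- dataset$manifest
  ids <- sort(names(manifest$items))
  relpaths <- vapply(ids, function(id) manifest$items[[id]]$relpath,
                     character(1))
  stored <- broker_stored_items(dataset$broker)
  missing_idx <- !(ids %in% stored$identifier)
  missing <- data.frame(identifier = ids[missing_idx],
                        relpath = unname(relpaths[missing_idx]),
                        stringsAsFactors = FALSE)
  unknown <- sort(setdiff(stored$identifier, ids))
  altered_size <- data.frame(identifier = character(0),
                             relpath = character(0),
                             stringsAsFactors = FALSE)
  altered_hash <- altered_size
  present <- ids[!missing_idx]
  for (id in present) {
    it <- manifest$items[[id]]
    stored_size <- stored$size_in_bytes[match(id, stored$identifier)]
    if (!isTRUE(stored_size == it$size_in_bytes)) {
      altered_size <- rbind(altered_size, data.frame(
        identifier = id, relpath = it$relpath, stringsAsFactors = FALSE
      ))
    }
    if (full) {
      digest <- broker_item_hash(dataset$broker, id, it$relpath,
                                 manifest$hash_function)
      if (!identical(digest, it$hash)) {
        altered_hash <- rbind(altered_hash, data.frame(
          identifier = id, relpath = it$relpath, stringsAsFactors = FALSE
        ))
      }
    }
  }
  ok <- nrow(missing) == 0L && length(unknown) == 0L &&
    nrow(altered_size) == 0L && nrow(altered_hash) == 0L
  structure(list(ok = ok, missing = missing, unknown = unknown,
                 altered_size = altered_size, altered_hash = altered_hash,
                 full = full),
            class = "dt_verify_report")
}

#' @export
print.dt_verify_report <- function(x, ...) {
  if (x$ok) {
    cat("All good :)\n")
    return(invisible(x))
  }
  for (i in seq_len(nrow(x$missing))) {
    cat(sprintf("Missing item: %s %s\n",
                x$missing$identifier[i], x$missing$relpath[i]))
  }
  for (id in x$unknown) {
    cat(sprintf("Unknown item: %s\n", id))
  }
  altered <- rbind(x$altered_size, x$altered_hash)
  altered <- altered[!duplicated(altered$identifier), , drop = FALSE]
  for (i in seq_len(nrow(altered))) {
    cat(sprintf("Altered item: %s %s\n",
                altered$identifier[i], altered$relpath[i]))
  }
  invisible(x)
}

#' Copy a dataset to another base location
#'
#' The copy is faithful: UUID, name, readme text, overlays and the manifest
#' (hash function, identifiers, relative paths, sizes, hashes, timestamps)
#' are preserved byte-for-byte, whatever the source and destination media.
#' The administrative record is written last, so an interrupted copy leaves a
#' location that is recognizably *not* a dataset rather than a plausible but
#' broken one.
#'
#' @param src_uri URI of a frozen dataset.
#' @param dest_base_uri Base location to copy into.
#' @return The destination dataset's URI (as text).
#' @export
copy_dataset <- function(src_uri, dest_base_uri) {
  src <- load_dataset(src_uri)
  base <- as_dt_uri(dest_base_uri)
  entry <- broker_entry(base$scheme)
  dest_uri <- entry$dataset_uri(base, src$admin$name, src$admin$uuid)
  dest_broker <- entry$new_broker(dest_uri)
  if (broker_exists(dest_broker)) {
    stop_collision(sprintf(
      "a dataset with UUID %s already exists at %s",
      read_admin(dest_broker)$uuid, dest_uri$uri
    ))
  }
  if (broker_location_occupied(dest_broker)) {
    stop_broker(sprintf("destination location %s is already occupied",
                        dest_uri$uri))
  }
  broker_create_structure(dest_broker)
  for (id in list_identifiers(src)) {
    it <- src$manifest$items[[id]]
    local_path <- fetch_item(src, id)
    broker_put_item(dest_broker, local_path, it$relpath)
  }
  broker_put_text(dest_broker, "manifest", broker_get_text(src$broker,
                                                           "manifest"))
  broker_put_text(dest_broker, "readme", read_readme(src))
  for (overlay_name in broker_list_overlay_names(src$broker)) {
    key <- paste0("overlay.", overlay_name)
    broker_put_text(dest_broker, key, broker_get_text(src$broker, key))
  }
  # admin record last: its presence is the marker of a complete dataset
  broker_put_text(dest_broker, "admin", broker_get_text(src$broker, "admin"))
  dest_uri$uri
}

#' Summarize a dataset
#'
#' @param dataset A `dt_dataset` handle.
#' @return A `dt_summary` with `name`, `uuid`, `creator_username`,
#'   `number_of_items`, `total_size_in_bytes` and `frozen_at` (UTC epoch
#'   seconds). Printing renders the summary as `key: value` lines with the
#'   size formatted with binary prefixes and the freeze time as a UTC ISO
#'   date.
#' @export
summarize_dataset <- function(dataset) {
  stopifnot(inherits(dataset, "dt_dataset"))
  sizes <- vapply(dataset$manifest$items, function(it) it$size_in_bytes,
                  numeric(1))
  structure(
    list(
      name = dataset$admin$name,
      uuid = dataset$admin$uuid,
      creator_username = dataset$admin$creator_username,
      number_of_items = length(dataset$manifest$items),
      total_size_in_bytes = if (length(sizes)) sum(sizes) else 0,
      frozen_at = as.numeric(dataset$admin$frozen_at)
    ),
    class = "dt_summary"
  )
}

#' @export
summary.dt_dataset <- function(object, ...) {
  summarize_dataset(object)
}

#' @export
print.dt_summary <- function(x, ...) {
  cat(sprintf("name: %s\n", x$name))
  cat(sprintf("uuid: %s\n", x$uuid))
  cat(sprintf("creator_username: %s\n", x$creator_username))
  cat(sprintf("number_of_items: %d\n", x$number_of_items))
  cat(sprintf("size: %s\n", format_size(x$total_size_in_bytes)))
  cat(sprintf("frozen_at: %s\n", iso_utc_date(x$frozen_at)))
  invisible(x)
}

#' @export
print.dt_dataset <- function(x, ...) {
  cat(sprintf("<dtoolr dataset '%s' at %s>\n", x$admin$name, x$uri$uri))
  cat(sprintf("  uuid: %s\n", x$admin$uuid))
  cat(sprintf("  items: %d\n", length(x$manifest$items)))
  invisible(x)
}

#' @export
print.dt_proto_dataset <- function(x, ...) {
  cat(sprintf("<dtoolr proto dataset '%s' at %s>\n", x$admin$name, x$uri$uri))
  invisible(x)
}

#' URI of a dataset handle
#'
#' @param dataset A `dt_dataset` or `dt_proto_dataset` handle.
#' @return The dataset's URI as text.
#' @export
dataset_uri <- function(dataset) {
  dataset$uri$uri
}
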