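# Dataset URIs and the storage-broker registry.
#
# Every dataset location is a URI. Bare paths are a convenience for people
# working at a shell and normalize to absolute "file://" URIs; other schemes
# are resolved through the broker registry so new storage backends can be
# plugged in without touching existing code.

.broker_registry <- new.env(parent = emptyenv())

#' Parse text into a dataset URI
#'
#' A bare path (no `scheme://`) is resolved against the working directory and
#' becomes a `file://` URI; normalization is idempotent, so feeding a
#' normalized URI back in returns it unchanged.
#'
#' @param text URI or local path.
#' @return An object of class `dt_uri` with fields `scheme`, `location`
#'   (path-like remainder) and `uri` (normalized text form).
#' @export
parse_uri <- function(text) {
  if (!is.character(text) || length(text) != 1L || is.na(text) ||
      !nzchar(text)) {
    stop_validation("URI must be non-empty text")
  }
  m <- regmatches(text, regexec("^([a-zA-Z][a-zA-Z0-9+.-]*)://(.*)$", text))[[1]]
  if (length(m) == 3L) {
    scheme <- tolower(m[2])
    location <- m[3]
  } else {
    scheme <- "file"
    location <- absolute_path(text)
  }
  if (scheme == "file" && !startsWith(location, "/")) {
    location <- absolute_path(location)
  }
  structure(
    list(scheme = scheme, location = location,
         uri = paste0(scheme, "://", location)),
    class = "dt_uri"
  )
}

# Absolute, cleaned path without requiring the leaf to exist.
absolute_path <- function(path) {
  path <- path.expand(path)
  if (!startsWith(path, "/")) {
    path <- file.path(getwd(), path)
  }
  # normalizePath collapses "." and ".." where the components exist
  normalizePath(path, winslash = "/", mustWork = FALSE)
}

#' @export
print.dt_uri <- function(x, ...) {
  cat(x$uri, "\n")
  invisible(x)
}

#' Register a storage-broker scheme
#'
#' Brokers map the dataset abstraction onto a concrete storage medium. A
#' scheme registration supplies constructors and base-URI helpers; dataset
#' logic only ever talks to brokers through the generic contract, so
#' registering a new scheme requires no change to existing code.
#'
#' @param scheme URI scheme, e.g. `"file"`.
#' @param new_broker Function `(uri)` returning a broker bound to one dataset
#'   location.
#' @param dataset_uri Function `(base_uri, name, uuid)` returning the URI a
#'   dataset with that name/UUID occupies under the base.
#' @param list_datasets Function `(base_uri)` returning a data frame with
#'   columns `name`, `uri`, `state` for datasets directly under the base.
#' @export
register_broker <- function(scheme, new_broker, dataset_uri, list_datasets) {
  assign(scheme,
         list(new_broker = new_broker, dataset_uri = dataset_uri,
              list_datasets = list_datasets),
         envir = .broker_registry)
  invisible(scheme)
}

registered_schemes <- function() {
  sort(ls(.broker_registry))
}

broker_entry <- function(scheme) {
  if (!exists(scheme, envir = .broker_registry, inherits = FALSE)) {
    stop_config(sprintf(
      "no storage broker registered for scheme '%s' (known schemes: %s)",
      scheme, paste(registered_schemes(), collapse = ", ")
    ))
  }
  get(scheme, envir = .broker_registry)
}

#' Obtain a broker for a dataset URI
#'
#' @param uri A `dt_uri` or text accepted by [parse_uri()].
#' @return A broker instance bound to that location.
#' @export
broker_for <- function(uri) {
  uri <- as_dt_uri(uri)
  broker_entry(uri$scheme)$new_broker(uri)
}

as_dt_uri <- function(uri) {
  if (inherits(uri, "dt_uri")) uri else parse_uri(uri)
}

#' List datasets under a base URI
#'
#' A base URI is a location under which several datasets live (a directory of
#' datasets, an object-store bucket). Rows are sorted by name, ties broken by
#' URI.
#'
#' @param base_uri Base location.
#' @return Data frame with columns `name`, `uri`, `state` (`"frozen"` or
#'   `"proto"`).
#' @export
list_datasets <- function(base_uri) {
  base_uri <- as_dt_uri(base_uri)
  out <- broker_entry(base_uri$scheme)$list_datasets(base_uri)
  out[order(out$name, out$uri), , drop = FALSE]
}

# -- Generic broker contract -------------------------------------------------
#
# All dataset-level reads and writes flow through these generics; concrete
# brokers define the on-medium representation.

broker_create_structure <- function(broker) UseMethod("broker_create_structure")
broker_exists <- function(broker) UseMethod("broker_exists")

# named text artefacts: admin record, manifest, readme, structure description,
# overlays. Keys are logical names; brokers decide where they live.
broker_put_text <- function(broker, key, text) UseMethod("broker_put_text")
broker_get_text <- function(broker, key) UseMethod("broker_get_text")
broker_has_text <- function(broker, key) UseMethod("broker_has_text")
broker_list_overlay_names <- function(broker) {
  UseMethod("broker_list_overlay_names")
}

# item payloads
broker_put_item <- function(broker, src_path, relpath) {
  UseMethod("broker_put_item")
}
# data frame (identifier, relpath, size_in_bytes, utc_timestamp) of what is
# actually in storage -- the source of truth at freeze and verify time
broker_stored_items <- function(broker) UseMethod("broker_stored_items")
# local readable path for an item, materializing to cache when non-local
broker_item_path <- function(broker, identifier, relpath) {
  UseMethod("broker_item_path")
}
# digest of the *stored* bytes (never a cached copy)
broker_item_hash <- function(broker, identifier, relpath, algorithm) {
  UseMethod("broker_item_hash")
}
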