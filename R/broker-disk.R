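# Filesystem broker: the canonical, human-auditable on-disk layout.
#
#   <dataset>/
#     README.yml            descriptive metadata (user-supplied YAML)
#     data/                 item payloads at their relative paths
#     .dtool/
#       dtool               administrative record (JSON)
#       manifest.json       structural metadata
#       structure.json      map of logical artefact names -> locations
#       README.txt          plain-language note that this is a dataset
#       overlays/<name>.json  per-item metadata overlays

DISK_STRUCTURE_README <- paste(
  "This directory is a dataset packaged with dtoolr.",
  "",
  "It bundles data files (under data/) with metadata:",
  "  - README.yml            descriptive metadata about the whole dataset",
  "  - .dtool/dtool          administrative metadata (UUID, name, state)",
  "  - .dtool/manifest.json  structural metadata (per-item size, checksum,",
  "                          relative path, timestamp)",
  "  - .dtool/overlays/      per-item descriptive metadata",
  "",
  "Do not edit the files under .dtool/ by hand; doing so can make the",
  "dataset fail verification. Use dtoolr (or any tool understanding this",
  "layout) to interact with the dataset.",
  "",
  sep = "\n"
)

new_disk_broker <- function(uri) {
  uri <- as_dt_uri(uri)
  structure(
    list(uri = uri, root = uri$location),
    class = c("dt_disk_broker", "dt_broker")
  )
}

disk_key_path <- function(broker, key) {
  root <- broker$root
  if (key == "readme") {
    return(file.path(root, "README.yml"))
  }
  if (key == "admin") {
    return(file.path(root, ".dtool", "dtool"))
  }
  if (key == "manifest") {
    return(file.path(root, ".dtool", "manifest.json"))
  }
  if (key == "structure") {
    return(file.path(root, ".dtool", "structure.json"))
  }
  if (key == "structure_readme") {
    return(file.path(root, ".dtool", "README.txt"))
  }
  if (startsWith(key, "overlay.")) {
    name <- sub("^overlay\\.", "", key)
    return(file.path(root, ".dtool", "overlays", paste0(name, ".json")))
  }
  stop_broker(sprintf("disk broker has no artefact key '%s'", key))
}

#' @export
broker_create_structure.dt_disk_broker <- function(broker) {
  if (dir.exists(broker$root) || file.exists(broker$root)) {
    stop_broker(sprintf("location already exists: %s", broker$uri$uri))
  }
  ok <- dir.create(broker$root, recursive = TRUE, showWarnings = FALSE)
  if (!ok) {
    stop_broker(sprintf("cannot create dataset directory at %s",
                        broker$uri$uri))
  }
  dir.create(file.path(broker$root, "data"), showWarnings = FALSE)
  dir.create(file.path(broker$root, ".dtool", "overlays"),
             recursive = TRUE, showWarnings = FALSE)
  write_text_file(file.path(broker$root, ".dtool", "README.txt"),
                  DISK_STRUCTURE_README)
  structure_map <- list(
    admin_record = ".dtool/dtool",
    data = "data",
    manifest = ".dtool/manifest.json",
    overlays = ".dtool/overlays",
    readme = "README.yml",
    structure_readme = ".dtool/README.txt"
  )
  write_text_file(
    file.path(broker$root, ".dtool", "structure.json"),
    structure_json(structure_map, broker_name = "disk")
  )
  invisible(broker)
}

structure_json <- function(map, broker_name) {
  map$broker <- broker_name
  map$broker_version <- as.character(utils::packageVersion("dtoolr"))
  map <- map[sort(names(map))]
  fields <- vapply(names(map), function(k) {
    paste0("  ", json_str(k), ": ", json_str(map[[k]]))
  }, character(1))
  paste0("{\n", paste(fields, collapse = ",\n"), "\n}\n")
}

#' @export
broker_exists.dt_disk_broker <- function(broker) {
  file.exists(disk_key_path(broker, "admin"))
}

broker_location_occupied <- function(broker) UseMethod("broker_location_occupied")

#' @export
broker_location_occupied.dt_disk_broker <- function(broker) {
  dir.exists(broker$root) || file.exists(broker$root)
}

#' @export
broker_put_text.dt_disk_broker <- function(broker, key, text) {
  path <- disk_key_path(broker, key)
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  write_text_file(path, text)
  invisible(broker)
}

#' @export
broker_get_text.dt_disk_broker <- function(broker, key) {
  path <- disk_key_path(broker, key)
  if (!file.exists(path)) {
    stop_not_found(sprintf("no '%s' artefact in dataset at %s", key,
                           broker$uri$uri))
  }
  read_text_file(path)
}

#' @export
broker_has_text.dt_disk_broker <- function(broker, key) {
  file.exists(disk_key_path(broker, key))
}

#' @export
broker_list_overlay_names.dt_disk_broker <- function(broker) {
  dir <- file.path(broker$root, ".dtool", "overlays")
  if (!dir.exists(dir)) {
    return(character(0))
  }
  sort(sub("\\.json$", "", list.files(dir, pattern = "\\.json$")))
}

#' @export
broker_put_item.dt_disk_broker <- function(broker, src_path, relpath) {
  dest <- file.path(broker$root, "data", relpath)
  dir.create(dirname(dest), recursive = TRUE, showWarnings = FALSE)
  # copy.date keeps the source modification time, which becomes the item's
  # utc_timestamp at freeze
  ok <- file.copy(src_path, dest, overwrite = TRUE, copy.date = TRUE)
  if (!ok) {
    stop_io(sprintf("failed to store '%s' as item '%s'", src_path, relpath))
  }
  invisible(generate_identifier(relpath))
}

#' @export
broker_stored_items.dt_disk_broker <- function(broker) {
  data_dir <- file.path(broker$root, "data")
  relpaths <- sort(list.files(data_dir, recursive = TRUE, all.files = TRUE))
  if (length(relpaths) == 0L) {
    return(data.frame(identifier = character(0), relpath = character(0),
                      size_in_bytes = numeric(0), utc_timestamp = numeric(0),
                      stringsAsFactors = FALSE))
  }
  info <- file.info(file.path(data_dir, relpaths))
  data.frame(
    identifier = vapply(relpaths, generate_identifier, character(1),
                        USE.NAMES = FALSE),
    relpath = relpaths,
    size_in_bytes = as.numeric(info$size),
    utc_timestamp = as.numeric(info$mtime),
    stringsAsFactors = FALSE
  )
}

#' @export
broker_item_path.dt_disk_broker <- function(broker, identifier, relpath) {
  path <- file.path(broker$root, "data", relpath)
  if (!file.exists(path)) {
    stop_not_found(sprintf("item '%s' (%s) not present in dataset at %s",
                           identifier, relpath, broker$uri$uri))
  }
  absolute_path(path)
}

#' @export
broker_item_hash.dt_disk_broker <- function(broker, identifier, relpath,
                                            algorithm) {
  hash_file_content(file.path(broker$root, "data", relpath), algorithm)$digest
}

disk_dataset_uri <- function(base_uri, name, uuid) {
  parse_uri(file.path(base_uri$location, name))
}

disk_list_datasets <- function(base_uri) {
  base <- base_uri$location
  entries <- if (dir.exists(base)) {
    list.dirs(base, recursive = FALSE, full.names = TRUE)
  } else {
    character(0)
  }
  rows <- lapply(entries, function(d) {
    admin_path <- file.path(d, ".dtool", "dtool")
    if (!file.exists(admin_path)) {
      return(NULL)
    }
    admin <- admin_from_json(read_text_file(admin_path))
    data.frame(name = admin$name, uri = parse_uri(d)$uri, state = admin$state,
               stringsAsFactors = FALSE)
  })
  rows <- Filter(Negate(is.null), rows)
  if (length(rows) == 0L) {
    return(data.frame(name = character(0), uri = character(0),
                      state = character(0), stringsAsFactors = FALSE))
  }
  do.call(rbind, rows)
}

# UTF-8 text file helpers shared by both brokers; byte-preserving (no
# newline mangling beyond what the caller supplies).
write_text_file <- function(path, text) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeBin(charToRaw(enc2utf8(text)), con)
}

read_text_file <- function(path) {
  raw <- readBin(path, "raw", n = file.size(path))
  txt <- rawToChar(raw)
  Encoding(txt) <- "UTF-8"
  txt
}
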