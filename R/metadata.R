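# Descriptive metadata: the dataset-level README (free-form YAML) and
# per-item overlays.
#
# The README is the user's own text and is stored byte-for-byte: it is never
# re-serialized, so comments and formatting survive, and a YAML parse failure
# never blocks storage or display. Overlays attach one scalar value per item,
# keyed by item identifier; they are how scripts annotate items
# programmatically (e.g. marking which member of a read pair each FASTQ file
# is).

#' Generate a README template for descriptive metadata
#'
#' The template is valid YAML and covers the questions a curator is asked
#' when creating a dataset: what the data is, which project it belongs to,
#' whether it is confidential or contains personally identifiable
#' information, who owns it and when it was created. The exact key set is a
#' repository convention.
#'
#' @param answers Optional named list overriding template defaults, e.g.
#'   `list(description = "RNA-seq of col0 leaves")`.
#' @return YAML text (starting with the `---` document marker).
#' @export
readme_template <- function(answers = NULL) {
  defaults <- list(
    description = "",
    project = "",
    confidential = FALSE,
    personally_identifiable_information = FALSE,
    owner_name = "",
    owner_email = "",
    creation_date = format(Sys.Date(), "%Y-%m-%d")
  )
  if (!is.null(answers)) {
    for (key in names(answers)) {
      defaults[[key]] <- answers[[key]]
    }
  }
  yaml_scalar <- function(v) {
    if (is.logical(v)) {
      return(if (v) "true" else "false")
    }
    v <- as.character(v)
    if (!nzchar(v)) {
      return('""')
    }
    v
  }
  paste0(
    "---\n",
    "description: ", yaml_scalar(defaults$description), "\n",
    "project: ", yaml_scalar(defaults$project), "\n",
    "confidential: ", yaml_scalar(defaults$confidential), "\n",
    "personally_identifiable_information: ",
    yaml_scalar(defaults$personally_identifiable_information), "\n",
    "owners:\n",
    "  - name: ", yaml_scalar(defaults$owner_name), "\n",
    "    email: ", yaml_scalar(defaults$owner_email), "\n",
    "creation_date: ", yaml_scalar(defaults$creation_date), "\n"
  )
}

#' Write or read a dataset's README
#'
#' Descriptive metadata is curatorial, not structural, so writing the README
#' is permitted on both proto and frozen datasets; structural metadata (the
#' manifest, the administrative record) stays immutable after freezing.
#'
#' @param dataset A `dt_dataset` or `dt_proto_dataset` handle.
#' @param text README content (normally YAML); stored byte-for-byte.
#' @return `read_readme()` returns the stored text exactly as written.
#' @export
write_readme <- function(dataset, text) {
  stopifnot(inherits(dataset, c("dt_dataset", "dt_proto_dataset")))
  if (!is.character(text) || length(text) != 1L || is.na(text)) {
    stop_validation("readme text must be a single character string")
  }
  broker_put_text(dataset$broker, "readme", text)
  invisible(dataset)
}

#' @rdname write_readme
#' @export
read_readme <- function(dataset) {
  stopifnot(inherits(dataset, c("dt_dataset", "dt_proto_dataset")))
  broker_get_text(dataset$broker, "readme")
}

#' Parse a dataset's README as YAML
#'
#' Best-effort convenience: returns `NULL` when the text is not valid YAML
#' (the raw text, available via [read_readme()], is always authoritative).
#'
#' @param dataset A dataset handle.
#' @return Parsed YAML (usually a named list) or `NULL`.
#' @export
parse_readme <- function(dataset) {
  tryCatch(yaml::yaml.load(read_readme(dataset)), error = function(e) NULL)
}

overlay_scalar_ok <- function(v) {
  is.null(v) ||
    (is.atomic(v) && length(v) == 1L &&
       (is.character(v) || is.numeric(v) || is.logical(v)))
}

#' Attach a per-item metadata overlay
#'
#' An overlay maps item identifiers to scalar values (text, number, boolean
#' or null). Every key must be an identifier in the dataset's manifest;
#' nested structures are rejected to keep overlays queryable.
#'
#' @param dataset A frozen `dt_dataset` handle.
#' @param name Overlay name (letters, digits, `"."`, `"-"`, `"_"`).
#' @param mapping Named list: identifier -> scalar value.
#' @return `get_overlay()` returns the stored mapping as a named list.
#' @export
put_overlay <- function(dataset, name, mapping) {
  stopifnot(inherits(dataset, "dt_dataset"))
  if (!grepl(SAFE_NAME_RE, name)) {
    stop_validation(sprintf("invalid overlay name '%s'", name))
  }
  if (!is.list(mapping) || (length(mapping) > 0L && is.null(names(mapping)))) {
    stop_validation("overlay mapping must be a named list")
  }
  known <- names(dataset$manifest$items)
  for (id in names(mapping)) {
    if (!(id %in% known)) {
      stop_validation(sprintf(
        "overlay key '%s' is not an item identifier of dataset at %s",
        id, dataset$uri$uri
      ))
    }
    if (!overlay_scalar_ok(mapping[[id]])) {
      stop_validation(sprintf(
        "overlay value for '%s' must be a scalar (text, number, boolean or null)",
        id
      ))
    }
  }
  broker_put_text(dataset$broker, paste0("overlay.", name),
                  overlay_to_json(mapping))
  invisible(dataset)
}

#' @rdname put_overlay
#' @export
get_overlay <- function(dataset, name) {
  stopifnot(inherits(dataset, "dt_dataset"))
  key <- paste0("overlay.", name)
  if (!broker_has_text(dataset$broker, key)) {
    stop_not_found(sprintf("no overlay named '%s' in dataset at %s",
                           name, dataset$uri$uri))
  }
  overlay_from_json(broker_get_text(dataset$broker, key))
}

#' List the overlays of a dataset
#'
#' @param dataset A `dt_dataset` handle.
#' @return Character vector of overlay names, sorted.
#' @export
list_overlays <- function(dataset) {
  stopifnot(inherits(dataset, "dt_dataset"))
  broker_list_overlay_names(dataset$broker)
}
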