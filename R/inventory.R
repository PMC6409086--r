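# Inventory reports: one row per frozen dataset under a base URI, rendered as
# HTML (self-contained static table), CSV or JSON. All three formats carry
# identical rows; generation is read-only.

inventory_rows <- function(base_uri) {
  listed <- list_datasets(base_uri)
  listed <- listed[listed$state == "frozen", , drop = FALSE]
  rows <- lapply(seq_len(nrow(listed)), function(i) {
    ds <- load_dataset(listed$uri[i])
    s <- summarize_dataset(ds)
    data.frame(
      name = s$name,
      uuid = s$uuid,
      creator_username = s$creator_username,
      number_of_items = s$number_of_items,
      size = format_size(s$total_size_in_bytes),
      frozen_at = iso_utc_date(s$frozen_at),
      uri = listed$uri[i],
      stringsAsFactors = FALSE
    )
  })
  if (length(rows) == 0L) {
    return(data.frame(
      name = character(0), uuid = character(0),
      creator_username = character(0), number_of_items = integer(0),
      size = character(0), frozen_at = character(0), uri = character(0),
      stringsAsFactors = FALSE
    ))
  }
  out <- do.call(rbind, rows)
  out[order(out$name, out$uri), , drop = FALSE]
}

html_escape <- function(s) {
  s <- gsub("&", "&amp;", s, fixed = TRUE)
  s <- gsub("<", "&lt;", s, fixed = TRUE)
  s <- gsub(">", "&gt;", s, fixed = TRUE)
  s
}

#' Build an inventory report of the datasets under a base URI
#'
#' @param base_uri Base location containing datasets.
#' @param format One of `"html"` (single self-contained page with one table),
#'   `"csv"` (header row, RFC-4180-style quoting) or `"json"` (array of row
#'   objects). All formats contain the same rows, sorted by dataset name.
#' @return The report as a single character string.
#' @export
build_inventory <- function(base_uri, format = c("html", "csv", "json")) {
  format <- match.arg(format)
  rows <- inventory_rows(base_uri)
  switch(format,
    csv = {
      con <- textConnection("out", "w", local = TRUE)
      utils::write.csv(rows, con, row.names = FALSE, quote = TRUE)
      close(con)
      paste0(paste(out, collapse = "\n"), "\n")
    },
    json = {
      as.character(jsonlite::toJSON(rows, dataframe = "rows", pretty = 2,
                                    auto_unbox = TRUE, digits = NA))
    },
    html = {
      header_cells <- paste0("      <th>", names(rows), "</th>",
                             collapse = "\n")
      body <- vapply(seq_len(nrow(rows)), function(i) {
        cells <- vapply(names(rows), function(col) {
          paste0("      <td>", html_escape(as.character(rows[[col]][i])),
                 "</td>")
        }, character(1))
        paste0("    <tr>\n", paste(cells, collapse = "\n"), "\n    </tr>")
      }, character(1))
      paste0(
        "<!DOCTYPE html>\n<html>\n<head>\n",
        "<meta charset=\"utf-8\">\n<title>Dataset inventory</title>\n",
        "<style>table{border-collapse:collapse}",
        "td,th{border:1px solid #888;padding:4px 8px;text-align:left}",
        "</style>\n</head>\n<body>\n",
        "<h1>Dataset inventory</h1>\n",
        "<table>\n  <thead>\n    <tr>\n", header_cells,
        "\n    </tr>\n  </thead>\n  <tbody>\n",
        if (length(body)) paste0(paste(body, collapse = "\n"), "\n") else "",
        "  </tbody>\n</table>\n</body>\n</html>\n"
      )
    }
  )
}
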