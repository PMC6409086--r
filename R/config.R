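# User-level configuration: creator username and item-cache root.
#
# Precedence (highest wins): environment variable, configuration file, built-in
# default. The configuration file is JSON with keys "creator_username" and
# "cache_root"; its location can itself be moved with DTOOLR_CONFIG.

default_config_path <- function() {
  Sys.getenv("DTOOLR_CONFIG",
             file.path(path.expand("~"), ".config", "dtoolr", "config.json"))
}

read_config_file <- function(path = default_config_path()) {
  if (!file.exists(path)) {
    return(list())
  }
  tryCatch(
    jsonlite::fromJSON(path, simplifyVector = TRUE),
    error = function(e) list()
  )
}

#' Resolve the creator username
#'
#' Used when creating proto datasets. Resolution order: the
#' `DTOOLR_CREATOR_USERNAME` environment variable, the `creator_username` key
#' in the user configuration file, then the operating-system account name.
#'
#' @return A single character string.
#' @export
dt_creator_username <- function() {
  env <- Sys.getenv("DTOOLR_CREATOR_USERNAME", "")
  if (nzchar(env)) {
    return(env)
  }
  cfg <- read_config_file()
  if (!is.null(cfg$creator_username) && nzchar(cfg$creator_username)) {
    return(as.character(cfg$creator_username))
  }
  unname(Sys.info()[["user"]])
}

#' Resolve the item cache root
#'
#' Directory under which non-filesystem brokers materialize item content so it
#' can be handed to tools as a local path. Resolution order: the
#' `DTOOLR_CACHE_ROOT` environment variable, the `cache_root` key in the user
#' configuration file, then `~/.cache/dtoolr`.
#'
#' @return Absolute path of the cache root (created on demand, not here).
#' @export
dt_cache_root <- function() {
  env <- Sys.getenv("DTOOLR_CACHE_ROOT", "")
  if (nzchar(env)) {
    return(env)
  }
  cfg <- read_config_file()
  if (!is.null(cfg$cache_root) && nzchar(cfg$cache_root)) {
    return(as.character(cfg$cache_root))
  }
  file.path(path.expand("~"), ".cache", "dtoolr")
}
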