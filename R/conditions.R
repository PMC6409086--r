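# Structured error conditions. Every user-facing failure mode gets its own
# condition class so callers (and the CLI) can react without parsing messages.

dt_error <- function(class, message, ..., call = NULL) {
  structure(
    class = c(class, "dtoolr_error", "error", "condition"),
    list(message = message, call = call, ...)
  )
}

stop_validation <- function(message, ...) {
  stop(dt_error("dtoolr_validation_error", message, ...))
}

stop_state <- function(message, ...) {
  stop(dt_error("dtoolr_state_error", message, ...))
}

stop_not_found <- function(message, ...) {
  stop(dt_error("dtoolr_not_found_error", message, ...))
}

stop_io <- function(message, ...) {
  stop(dt_error("dtoolr_io_error", message, ...))
}

stop_config <- function(message, ...) {
  stop(dt_error("dtoolr_config_error", message, ...))
}

stop_collision <- function(message, ...) {
  stop(dt_error("dtoolr_collision_error", message, ...))
}

stop_broker <- function(message, ...) {
  stop(dt_error("dtoolr_broker_error", message, ...))
}
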