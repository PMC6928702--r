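# Classed conditions so callers (and the CLI) can map failures to exit codes.

gb_condition <- function(class, message, call = sys.call(-1)) {
  structure(
    class = c(class, "gaitbouts_error", "error", "condition"),
    list(message = message, call = call)
  )
}

stop_format <- function(message) stop(gb_condition("gaitbouts_format_error", message))
stop_data <- function(message) stop(gb_condition("gaitbouts_data_error", message))
stop_param <- function(message) stop(gb_condition("gaitbouts_parameter_error", message))
stop_degenerate <- function(message) stop(gb_condition("gaitbouts_degenerate_signal_error", message))
stop_tuning <- function(message) stop(gb_condition("gaitbouts_tuning_error", message))
stop_config <- function(message) stop(gb_condition("gaitbouts_config_error", message))

warn_gb <- function(class, message) {
  warning(structure(
    class = c(class, "gaitbouts_warning", "warning", "condition"),
    list(message = message, call = sys.call(-1))
  ))
}
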