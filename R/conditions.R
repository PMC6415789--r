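# Classed conditions so callers (and the command-line wrapper) can map
# failure modes to exit codes without string matching.
abort_siplabel <- function(message, class, ...) {
  rlang::abort(message, class = c(class, "siplabel_error"), ...)
}

stop_validation <- function(message, ...) {
  abort_siplabel(message, "siplabel_error_validation", ...)
}

stop_format <- function(message, ...) {
  abort_siplabel(message, "siplabel_error_format", ...)
}

stop_config <- function(message, ...) {
  abort_siplabel(message, "siplabel_error_config", ...)
}

stop_io <- function(message, ...) {
  abort_siplabel(message, "siplabel_error_io", ...)
}

stop_undefined <- function(message, ...) {
  abort_siplabel(message, "siplabel_error_undefined", ...)
}
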