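# classed conditions so callers/tests can distinguish failure modes
abort_eospec <- function(msg, class) {
  stop(structure(
    class = c(class, "eospec_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

abort_format    <- function(msg) abort_eospec(msg, "eospec_error_format")
abort_dimension <- function(msg) abort_eospec(msg, "eospec_error_dimension")
abort_parameter <- function(msg) abort_eospec(msg, "eospec_error_parameter")
abort_data      <- function(msg) abort_eospec(msg, "eospec_error_data")
abort_selection <- function(msg) abort_eospec(msg, "eospec_error_selection")
abort_generation <- function(msg) abort_eospec(msg, "eospec_error_generation")

gaussian_curve <- function(lambda, center, sd) {
  exp(-(lambda - center)^2 / (2 * sd^2))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
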