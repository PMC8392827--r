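# Classed error conditions so callers (and tests) can distinguish
# bad inputs from numerical failures.

ferm_abort <- function(class, msg) {
  stop(errorCondition(msg, class = c(class, "fermco2_error", "error")))
}

abort_invalid     <- function(msg) ferm_abort("fermco2_invalid_input", msg)
abort_range       <- function(msg) ferm_abort("fermco2_range_error", msg)
abort_integration <- function(msg) ferm_abort("fermco2_integration_error", msg)
abort_metric      <- function(msg) ferm_abort("fermco2_metric_error", msg)
abort_optim       <- function(msg) ferm_abort("fermco2_optimization_error", msg)
abort_parse       <- function(msg) ferm_abort("fermco2_parse_error", msg)

check_finite <- function(x, what) {
  if (!is.numeric(x) || anyNA(x) || any(!is.finite(x))) {
    abort_invalid(sprintf("%s must be finite numeric", what))
  }
  invisible(x)
}
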