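#' Integral absolute error between two CO2 series
#'
#' The identification objective: the time integral of the absolute
#' difference between the measured and the simulated dissolved-CO2
#' series, evaluated by the trapezoidal rule on the shared sample grid.
#'
#' @param measured,simulated CO2 concentrations, g/L, on the same grid.
#' @param times Sample times, h, strictly increasing, length >= 2.
#' @return IAE, g.h/L; zero iff the series are identical on the grid.
#' @export
#' @examples
#' t <- seq(0, 24, by = 1/6)
#' iae(rep(0.002, length(t)), rep(0.001, length(t)), t)  # |e| * T = 0.024
iae <- function(measured, simulated, times) {
  check_finite(measured, "measured"); check_finite(simulated, "simulated")
  check_finite(times, "times")
  n <- length(times)
  if (n < 2L) abort_invalid("need at least 2 samples to integrate")
  if (length(measured) != n || length(simulated) != n) {
    abort_invalid("measured, simulated and times must have equal length")
  }
  if (any(diff(times) <= 0)) abort_invalid("times must be strictly increasing")
  e <- abs(measured - simulated)
  sum(diff(times) * (e[-1] + e[-n]) / 2)
}
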