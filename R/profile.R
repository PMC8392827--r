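#' Piecewise-constant temperature protocol
#'
#' The reference-temperature input u(t) of the heating/cooling system,
#' represented as right-continuous piecewise-constant breakpoints.  The
#' simulator restarts integration at each breakpoint so the discontinuity
#' is resolved exactly.
#'
#' @param times Breakpoint times, h; strictly increasing, first must be 0.
#' @param temps Reference temperature on `[times[i], times[i+1])`, degC.
#' @param window Validity window for temperatures, degC (milk fermentation
#'   runs in a narrow band; the default guards against unit mistakes).
#' @return Object of class `temperature_profile`.
#' @export
#' @examples
#' temperature_profile(c(0, 3), c(22, 27))
temperature_profile <- function(times, temps, window = c(4, 40)) {
  check_finite(times, "breakpoint times"); check_finite(temps, "temperatures")
  if (length(times) != length(temps) || length(times) < 1L) {
    abort_invalid("times and temps must have equal positive length")
  }
  if (times[1] != 0) abort_invalid("first breakpoint time must be 0")
  if (any(diff(times) <= 0)) abort_invalid("breakpoint times must be strictly increasing")
  if (any(temps < window[1] | temps > window[2])) {
    abort_range(sprintf("temperatures must lie within [%g, %g] degC",
                        window[1], window[2]))
  }
  structure(list(times = as.numeric(times), temps = as.numeric(temps),
                 window = window),
            class = "temperature_profile")
}

#' Step-change temperature protocol
#'
#' Reference temperature `theta_start` on `[0, t_step)` and `theta_end`
#' from `t_step` on (right-continuous).  `t_step = 0` gives a constant
#' `theta_end` protocol.
#'
#' @param theta_start,theta_end Temperatures before/after the step, degC.
#' @param t_step Step time, h (>= 0).
#' @param window Passed to [temperature_profile()].
#' @return A `temperature_profile`.
#' @export
#' @examples
#' make_step_profile(22, 27, 3)   # the canonical identification protocol
make_step_profile <- function(theta_start, theta_end, t_step,
                              window = c(4, 40)) {
  check_finite(t_step, "t_step")
  if (t_step < 0) abort_invalid("t_step must be >= 0")
  if (t_step == 0 || theta_start == theta_end) {
    temperature_profile(0, if (t_step == 0) theta_end else theta_start,
                        window)
  } else {
    temperature_profile(c(0, t_step), c(theta_start, theta_end), window)
  }
}

#' Constant temperature protocol
#' @param temperature Reference temperature, degC.
#' @param window Passed to [temperature_profile()].
#' @return A `temperature_profile`.
#' @export
make_constant_profile <- function(temperature, window = c(4, 40)) {
  temperature_profile(0, temperature, window)
}

#' Evaluate a temperature protocol
#'
#' @param profile A [temperature_profile()].
#' @param t Times, h (vectorized, all >= 0).
#' @return Reference temperature(s) at `t`, degC (value of the last
#'   breakpoint with time <= t; right-continuous).
#' @export
evaluate_profile <- function(profile, t) {
  check_finite(t, "t")
  if (any(t < 0)) abort_range("profile evaluation times must be >= 0")
  profile$temps[findInterval(t, profile$times)]
}

is_constant_profile <- function(profile) {
  length(unique(profile$temps)) == 1L
}

#' @export
print.temperature_profile <- function(x, ...) {
  cat("Temperature protocol (piecewise constant, right-continuous):\n")
  for (i in seq_along(x$times)) {
    cat(sprintf("  t >= %g h : %g degC\n", x$times[i], x$temps[i]))
  }
  invisible(x)
}
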