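#' Generate a synthetic measured experiment
#'
#' Emulates a laboratory fermentation run: integrates the 4-state
#' temperature-considered model under the given protocol, samples the
#' dissolved-CO2 state on a uniform grid (default 10-min spacing, the
#' laboratory acquisition rate), optionally adds independent Gaussian
#' sensor noise, and optionally passes the noisy series through a
#' discrete first-order low-pass filter emulating the analog anti-noise
#' filter of the acquisition chain.  The generating truth is recorded in
#' the `meta` attribute.
#'
#' An optional multiplicative electrode drift (`drift_per_5C`, fractional
#' slope change per 5 degC of temperature deviation from `theta_0`) is
#' available for calibration-realism studies and is off by default.
#'
#' @param params A [kinetic_parameters()] object.
#' @param coupling A [temperature_coupling()] object.
#' @param init Initial concentrations `c(x1, x2, x3)`, g/L.
#' @param profile A [temperature_profile()].
#' @param t_end Horizon, h.
#' @param dt_sample Sampling interval, h (default 1/6 h = 10 min).
#' @param noise_sd Sensor noise standard deviation, g/L.  `NULL` (the
#'   default) uses 2 percent of the noiseless signal range; `0` disables
#'   noise.
#' @param filter_tau First-order low-pass time constant, h; `0` disables
#'   the filter.
#' @param seed Optional integer seed for the noise draws.
#' @param drift_per_5C Fractional multiplicative drift per 5 degC (default 0).
#' @param rtol,atol Solver tolerances.
#' @return A data frame of class `measured_dataset` with columns
#'   `time_h`, `co2_gL`, `ref_temp_C`, `temp_C`, attribute `profile`, and
#'   attribute `meta` (generating parameters, noise settings, seed, and
#'   the noiseless truth `co2_true_gL`).
#' @export
#' @examples
#' ds <- generate_experiment(reference_parameters(), reference_coupling(),
#'                           reference_initial_state()[1:3],
#'                           make_step_profile(22, 27, 3),
#'                           noise_sd = 0, seed = 1)
#' head(ds)
generate_experiment <- function(params, coupling, init, profile,
                                t_end = 24, dt_sample = 1 / 6,
                                noise_sd = NULL, filter_tau = 0,
                                seed = NULL, drift_per_5C = 0,
                                rtol = 1e-8, atol = 1e-10) {
  if (dt_sample <= 0) abort_invalid("dt_sample must be > 0")
  if (filter_tau < 0) abort_invalid("filter_tau must be >= 0")
  times <- seq(0, t_end, by = dt_sample)
  tr <- simulate_fermentation(params, init, coupling = coupling,
                              profile = profile, t_end = t_end,
                              output_times = times, rtol = rtol, atol = atol)
  truth <- tr$x3_gL
  if (is.null(noise_sd)) noise_sd <- 0.02 * diff(range(truth))
  if (noise_sd < 0) abort_invalid("noise_sd must be >= 0")
  if (!is.null(seed)) set.seed(seed)
  co2 <- truth
  if (drift_per_5C != 0) {
    co2 <- co2 * (1 + drift_per_5C * (tr$temp_C - coupling$theta_0) / 5)
  }
  if (noise_sd > 0) co2 <- co2 + rnorm(length(co2), sd = noise_sd)
  if (filter_tau > 0) co2 <- lowpass_filter(co2, dt_sample, filter_tau)

  out <- data.frame(time_h = tr$time_h, co2_gL = co2,
                    ref_temp_C = tr$ref_temp_C, temp_C = tr$temp_C)
  structure(out,
            profile = profile,
            meta = list(params = params, coupling = coupling,
                        init = init[1:3], t_end = t_end,
                        dt_sample = dt_sample, noise_sd = noise_sd,
                        filter_tau = filter_tau, seed = seed,
                        drift_per_5C = drift_per_5C,
                        co2_true_gL = truth),
            class = c("measured_dataset", "data.frame"))
}

# y[k] = a y[k-1] + (1-a) x[k], a = exp(-dt/tau); y[1] = x[1]
lowpass_filter <- function(x, dt, tau) {
  a <- exp(-dt / tau)
  y <- x
  for (k in seq_along(x)[-1]) y[k] <- a * y[k - 1] + (1 - a) * x[k]
  y
}

#' Canonical reference datasets of the studied bioreactor
#'
#' The two fixtures used throughout identification and testing, built
#' from the reference configuration ([reference_parameters()],
#' [reference_coupling()], [reference_initial_state()]): a 24-h run at
#' constant 22 degC, and a 24-h run with a reference-temperature step
#' 22 to 27 degC at `step_time` (3 h is the identification protocol,
#' 6 h the validation protocol).  Both sample every 10 min and are
#' noiseless by default.
#'
#' @param seed Seed for the noise draws (irrelevant when `noise_sd = 0`).
#' @param noise_sd Sensor noise sd, g/L (default 0: noiseless fixture).
#' @param step_time Step time, h, strictly inside (0, 24).
#' @return A `measured_dataset`.
#' @export
#' @examples
#' ds <- reference_constant_dataset()
#' range(ds$ref_temp_C)
reference_constant_dataset <- function(seed = NULL, noise_sd = 0) {
  generate_experiment(reference_parameters(), reference_coupling(),
                      reference_initial_state()[1:3],
                      make_constant_profile(22),
                      noise_sd = noise_sd, seed = seed)
}

#' @rdname reference_constant_dataset
#' @export
reference_step_dataset <- function(step_time = 3, seed = NULL, noise_sd = 0) {
  if (step_time <= 0 || step_time >= 24) {
    abort_invalid("step_time must lie strictly inside (0, 24) h")
  }
  generate_experiment(reference_parameters(), reference_coupling(),
                      reference_initial_state()[1:3],
                      make_step_profile(22, 27, step_time),
                      noise_sd = noise_sd, seed = seed)
}

validate_dataset <- function(dataset) {
  if (!inherits(dataset, "measured_dataset")) {
    abort_invalid("expected a measured_dataset (see generate_experiment/read_dataset)")
  }
  if (is.null(attr(dataset, "profile"))) {
    abort_invalid("dataset is missing its temperature profile")
  }
  invisible(dataset)
}
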