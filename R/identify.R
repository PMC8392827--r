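#' Default identification bounds
#'
#' Broad search boxes for the two identification stages, deliberately not
#' centred on any known parameter set: the six kinetic constants span two
#' to four decades; the temperature coefficients start at zero (no
#' coupling) and the heating time constant spans 0.01-1 h.
#'
#' @return Named list with `lower` and `upper` vectors.
#' @export
stage1_bounds <- function() {
  list(lower = c(mu_m = 0.1, P_i = 0.01, S_m = 1e-4, S_i = 0.01,
                 alpha = 0.01, beta = 1e-5),
       upper = c(mu_m = 10, P_i = 5, S_m = 1, S_i = 10,
                 alpha = 2, beta = 0.1))
}

#' @rdname stage1_bounds
#' @export
stage2_bounds <- function() {
  list(lower = c(k_mu = 0, k_alpha = 0, T_theta_cs = 0.01),
       upper = c(k_mu = 1, k_alpha = 0.5, T_theta_cs = 1))
}

# zero lower bounds are allowed for the coupling coefficients (k = 0 means
# "no temperature effect"), so widen them infinitesimally for pso_config,
# which requires lower < upper but tolerates points on the boundary.
default_stage_config <- function(bounds, seed) {
  pso_config(lower = bounds$lower, upper = bounds$upper,
             swarm_size = 10L * length(bounds$lower), seed = seed)
}

dataset_objective <- function(dataset, init, params_template = NULL,
                              coupling = NULL, rtol, atol) {
  times <- dataset$time_h
  co2 <- dataset$co2_gL
  profile <- attr(dataset, "profile")
  t_end <- max(times)
  function(make_args) {
    tr <- tryCatch(
      simulate_fermentation(make_args$params, init,
                            coupling = make_args$coupling,
                            profile = profile, t_end = t_end,
                            output_times = times,
                            rtol = rtol, atol = atol),
      fermco2_error = function(e) NULL)
    if (is.null(tr)) return(Inf)
    iae(co2, tr$x3_gL, times)
  }
}

#' Stage-1 identification of the six kinetic parameters
#'
#' Fits `(mu_m, P_i, S_m, S_i, alpha, beta)` of the fundamental 3-state
#' model to a constant-temperature CO2 time course by minimizing the
#' [iae()] objective with [pso_minimize()].  Initial concentrations are
#' treated as known measured inputs, not identified.  Only the CO2
#' channel enters the objective.
#'
#' Because the six parameters are positive and their plausible ranges
#' span two to four decades, the swarm searches the box on a log scale
#' (the bounds in `config` are given and reported in natural units; only
#' the internal coordinates are logarithmic).  This conditions the search
#' without changing the admissible region.
#'
#' @param dataset A `measured_dataset` (see [generate_experiment()] or
#'   [read_dataset()]) whose temperature protocol is constant.
#' @param init Initial state `c(x1, x2, x3)`, g/L.
#' @param config A [pso_config()]; defaults to swarm 60 over
#'   [stage1_bounds()].
#' @param seed Convenience seed used when `config` is `NULL`.
#' @param rtol,atol Solver tolerances for the objective simulations.
#' @return List of class `identification_result`: `estimate`
#'   ([kinetic_parameters()]), `objective_value` (IAE, g.h/L),
#'   `iterations`, `history`, `seed`, `bounds`, `stage`.
#' @export
identify_stage1 <- function(dataset, init, config = NULL, seed = NULL,
                            rtol = 1e-8, atol = 1e-10) {
  validate_dataset(dataset)
  if (nrow(dataset) < 2L) abort_invalid("dataset must contain at least 2 samples")
  profile <- attr(dataset, "profile")
  if (!is_constant_profile(profile)) {
    abort_invalid("stage 1 requires a constant-temperature dataset")
  }
  b <- stage1_bounds()
  if (is.null(config)) config <- default_stage_config(b, seed)
  if (any(config$lower <= 0)) {
    abort_invalid("stage-1 bounds must be strictly positive (log-scale search)")
  }
  obj_env <- dataset_objective(dataset, init, rtol = rtol, atol = atol)
  objective <- function(z) {
    v <- exp(z)
    p <- kinetic_parameters(v[1], v[2], v[3], v[4], v[5], v[6])
    obj_env(list(params = p, coupling = NULL))
  }
  log_config <- config
  log_config$lower <- log(config$lower)
  log_config$upper <- log(config$upper)
  res <- pso_minimize(objective, log_config)
  res$par <- exp(res$par)
  est <- kinetic_parameters(res$par[1], res$par[2], res$par[3],
                            res$par[4], res$par[5], res$par[6])
  identification_result(est, res, config, stage = "stage1")
}

#' Stage-2 identification of the temperature-coupling parameters
#'
#' Fits `(k_mu, k_alpha, T_theta_cs)` of the 4-state temperature-
#' considered model to a CO2 time course recorded under a protocol with
#' at least one temperature change, holding the six kinetic parameters
#' fixed at the stage-1 values throughout.  `theta_0` is fixed to the
#' protocol's initial temperature, not identified.
#'
#' @param dataset A `measured_dataset` with a non-constant protocol.
#' @param stage1_params [kinetic_parameters()] from stage 1 (held fixed).
#' @param init Initial state `c(x1, x2, x3)`; x4(0) is taken as the
#'   protocol's initial temperature.
#' @param config A [pso_config()]; defaults to swarm 30 over
#'   [stage2_bounds()].
#' @inheritParams identify_stage1
#' @return List of class `identification_result` with `estimate` a
#'   [temperature_coupling()].
#' @export
identify_stage2 <- function(dataset, stage1_params, init, config = NULL,
                            seed = NULL, rtol = 1e-8, atol = 1e-10) {
  validate_dataset(dataset)
  if (nrow(dataset) < 2L) abort_invalid("dataset must contain at least 2 samples")
  profile <- attr(dataset, "profile")
  if (is_constant_profile(profile)) {
    abort_invalid(paste("stage 2 requires a dataset with a temperature change;",
                        "the coupling is unidentifiable at constant temperature"))
  }
  theta_0 <- profile$temps[1]
  b <- stage2_bounds()
  if (is.null(config)) config <- default_stage_config(b, seed)
  obj_env <- dataset_objective(dataset, c(init[1:3], x4 = theta_0),
                               rtol = rtol, atol = atol)
  objective <- function(v) {
    cp <- temperature_coupling(v[1], v[2], v[3], theta_0)
    obj_env(list(params = stage1_params, coupling = cp))
  }
  res <- pso_minimize(objective, config)
  est <- temperature_coupling(res$par[1], res$par[2], res$par[3], theta_0)
  identification_result(est, res, config, stage = "stage2")
}

#' Two-stage identification of all nine model parameters
#'
#' Runs [identify_stage1()] on the constant-temperature experiment, then
#' [identify_stage2()] on the step-temperature experiment with the
#' stage-1 estimate held fixed.
#'
#' @param dataset_const Constant-temperature `measured_dataset`.
#' @param dataset_step Step-temperature `measured_dataset`.
#' @param init Initial concentrations `c(x1, x2, x3)`, g/L.
#' @param config1,config2 Optional [pso_config()]s for the two stages.
#' @inheritParams identify_stage1
#' @return List of class `two_stage_result` with elements `params`
#'   ([kinetic_parameters()]), `coupling` ([temperature_coupling()]),
#'   `stage1`, `stage2` (the per-stage `identification_result`s).
#' @export
identify_two_stage <- function(dataset_const, dataset_step, init,
                               config1 = NULL, config2 = NULL, seed = NULL,
                               rtol = 1e-8, atol = 1e-10) {
  s1 <- identify_stage1(dataset_const, init, config = config1, seed = seed,
                        rtol = rtol, atol = atol)
  s2 <- identify_stage2(dataset_step, s1$estimate, init, config = config2,
                        seed = if (is.null(seed)) NULL else seed + 1L,
                        rtol = rtol, atol = atol)
  structure(list(params = s1$estimate, coupling = s2$estimate,
                 stage1 = s1, stage2 = s2),
            class = "two_stage_result")
}

identification_result <- function(estimate, pso_res, config, stage) {
  structure(list(estimate = estimate,
                 objective_value = pso_res$value,
                 iterations = pso_res$iterations,
                 history = pso_res$history,
                 evaluations = pso_res$evaluations,
                 seed = config$seed,
                 bounds = list(lower = config$lower, upper = config$upper),
                 stage = stage),
            class = "identification_result")
}

#' @export
print.identification_result <- function(x, ...) {
  cat(sprintf("%s identification: IAE %.6g g.h/L after %d iterations\n",
              x$stage, x$objective_value, x$iterations))
  print(x$estimate)
  invisible(x)
}

#' @export
print.two_stage_result <- function(x, ...) {
  cat("Two-stage identification\n")
  print(x$stage1); print(x$stage2)
  invisible(x)
}
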