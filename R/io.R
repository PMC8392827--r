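#' Load a run configuration from YAML
#'
#' Reads a hierarchical YAML configuration describing a model instance
#' and experiment.  Recognized sections:
#' \describe{
#'   \item{parameters}{`mu_m, P_i, S_m, S_i, alpha, beta` (g/L, 1/h).}
#'   \item{coupling}{`k_mu, k_alpha, T_theta_cs, theta_0` (optional).}
#'   \item{initial_state}{`unit` (`"g/L"` or `"mg/L"`), `x1, x2, x3`,
#'     optional `temp_C`.  mg/L values are converted to the canonical
#'     internal unit g/L on load.}
#'   \item{protocol}{either `type: constant` with `temperature`, or
#'     `type: step` with `theta_start, theta_end, t_step`.}
#'   \item{simulation}{optional `t_end`, `dt_sample`, `rtol`, `atol`.}
#'   \item{pso_stage1 / pso_stage2}{optional PSO overrides
#'     (`swarm_size`, `max_iterations`, `stall_iterations`,
#'     `function_tolerance`).}
#'   \item{seed}{optional integer.}
#' }
#' Validation errors name the offending key.
#'
#' @param path Path to a YAML file.
#' @return List of class `run_config` with elements `params`, `coupling`
#'   (or `NULL`), `init` (g/L, with `x4` when a temperature is given),
#'   `profile`, `simulation`, `pso_stage1`, `pso_stage2`, `seed`.
#' @export
load_config <- function(path) {
  raw <- yaml::read_yaml(path)
  need <- function(section, keys) {
    sec <- raw[[section]]
    if (is.null(sec)) abort_parse(sprintf("config is missing section '%s'", section))
    for (k in keys) {
      if (is.null(sec[[k]]) || !is.numeric(sec[[k]])) {
        abort_parse(sprintf("config key '%s.%s' is missing or non-numeric",
                            section, k))
      }
    }
    sec
  }

  ps <- need("parameters", c("mu_m", "P_i", "S_m", "S_i", "alpha", "beta"))
  params <- kinetic_parameters(ps$mu_m, ps$P_i, ps$S_m, ps$S_i,
                               ps$alpha, ps$beta)

  coupling <- NULL
  if (!is.null(raw$coupling)) {
    cs <- need("coupling", c("k_mu", "k_alpha", "T_theta_cs"))
    theta_0 <- if (is.null(cs$theta_0)) 22 else cs$theta_0
    coupling <- temperature_coupling(cs$k_mu, cs$k_alpha, cs$T_theta_cs,
                                     theta_0)
  }

  is_ <- need("initial_state", c("x1", "x2", "x3"))
  unit <- is_$unit
  if (is.null(unit) || !unit %in% c("g/L", "mg/L")) {
    abort_parse("config key 'initial_state.unit' must be \"g/L\" or \"mg/L\"")
  }
  scale <- if (unit == "mg/L") 1e-3 else 1
  init <- fermentation_state(is_$x1 * scale, is_$x2 * scale, is_$x3 * scale,
                             x4 = is_$temp_C)

  pr <- raw$protocol
  if (is.null(pr) || is.null(pr$type)) {
    abort_parse("config is missing 'protocol.type'")
  }
  profile <- switch(pr$type,
    constant = {
      if (is.null(pr$temperature)) abort_parse("config key 'protocol.temperature' is missing")
      make_constant_profile(pr$temperature)
    },
    step = {
      for (k in c("theta_start", "theta_end", "t_step")) {
        if (is.null(pr[[k]])) abort_parse(sprintf("config key 'protocol.%s' is missing", k))
      }
      make_step_profile(pr$theta_start, pr$theta_end, pr$t_step)
    },
    abort_parse(sprintf("unknown protocol.type '%s'", pr$type)))

  sim_defaults <- list(t_end = 24, dt_sample = 1 / 6, rtol = 1e-8, atol = 1e-10)
  sim <- utils::modifyList(sim_defaults, as.list(raw$simulation))

  structure(list(params = params, coupling = coupling, init = init,
                 profile = profile, simulation = sim,
                 pso_stage1 = as.list(raw$pso_stage1),
                 pso_stage2 = as.list(raw$pso_stage2),
                 seed = raw$seed),
            class = "run_config")
}

#' Write / read a measured dataset as CSV
#'
#' Columns `time_h`, `co2_gL`, `ref_temp_C` and (if present) `temp_C`;
#' times in hours, temperatures in degC, concentrations in g/L.
#' Generating metadata, when present, is written to a JSON sidecar.
#' `read_dataset()` validates column names, strictly increasing uniform
#' sampling, and finite values, and reconstructs the temperature profile
#' from the `ref_temp_C` column.
#'
#' @param dataset A `measured_dataset`.
#' @param path CSV file path.
#' @param meta_path Optional path for the JSON metadata sidecar.
#' @return `write_dataset()` the path, invisibly; `read_dataset()` a
#'   `measured_dataset`.
#' @export
write_dataset <- function(dataset, path, meta_path = NULL) {
  validate_dataset(dataset)
  utils::write.csv(as.data.frame(dataset), path, row.names = FALSE)
  if (!is.null(meta_path)) {
    meta <- attr(dataset, "meta")
    meta$params <- unclass(meta$params)
    meta$coupling <- unclass(meta$coupling)
    jsonlite::write_json(meta, meta_path, auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' @rdname write_dataset
#' @export
read_dataset <- function(path) {
  df <- utils::read.csv(path)
  required <- c("time_h", "co2_gL", "ref_temp_C")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols)) {
    abort_parse(sprintf("dataset is missing column(s): %s",
                        paste(missing_cols, collapse = ", ")))
  }
  extra <- setdiff(names(df), c(required, "temp_C"))
  if (length(extra)) {
    abort_parse(sprintf("dataset has unrecognized column(s): %s",
                        paste(extra, collapse = ", ")))
  }
  t <- df$time_h
  if (anyNA(df) || any(!is.finite(t)) || any(!is.finite(df$co2_gL))) {
    abort_parse("dataset contains missing or non-finite values")
  }
  dt <- diff(t)
  if (any(dt <= 0)) abort_parse("dataset times must be strictly increasing")
  if (diff(range(dt)) > 1e-6 * mean(dt)) {
    abort_parse("dataset sampling must be uniform")
  }
  chg <- c(TRUE, diff(df$ref_temp_C) != 0)
  profile <- temperature_profile(t[chg] - t[1], df$ref_temp_C[chg])
  structure(df, profile = profile, meta = NULL,
            class = c("measured_dataset", "data.frame"))
}

#' Write a simulated trajectory as CSV
#'
#' Columns `time_h`, `x1_gL`, `x2_gL`, `x3_gL`, `temp_C`, `ref_temp_C`.
#'
#' @param trajectory A `fermentation_trajectory`.
#' @param path CSV file path.
#' @return The path, invisibly.
#' @export
write_trajectory <- function(trajectory, path) {
  utils::write.csv(as.data.frame(trajectory), path, row.names = FALSE)
  invisible(path)
}

#' Write / read an identification result as JSON
#'
#' Serializes the estimate (names, values, units), the final IAE, the
#' iteration count, the convergence history, the seed and the bounds.
#'
#' @param result An `identification_result`.
#' @param path JSON file path.
#' @return `write_result()` the path, invisibly; `read_result()` a list.
#' @export
write_result <- function(result, path) {
  est <- unclass(result$estimate)
  units <- if (result$stage == "stage1") {
    c(mu_m = "1/h", P_i = "g/L", S_m = "g/L", S_i = "g/L",
      alpha = "g/L per g/L", beta = "1/h")
  } else {
    c(k_mu = "1/degC", k_alpha = "1/degC", T_theta_cs = "h",
      theta_0 = "degC")
  }
  out <- list(stage = result$stage,
              estimate = est,
              units = as.list(units[names(est)]),
              objective_iae_ghL = result$objective_value,
              iterations = result$iterations,
              history = result$history,
              seed = result$seed,
              bounds = result$bounds)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_result
#' @export
read_result <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}

#' Export a convergence history as CSV
#'
#' Two columns, `iteration` and `best_iae_ghL`: the best IAE value after
#' each PSO iteration.
#'
#' @param result An `identification_result` or `pso_result`.
#' @param path CSV file path.
#' @return The path, invisibly.
#' @export
write_history <- function(result, path) {
  utils::write.csv(data.frame(iteration = seq_along(result$history),
                              best_iae_ghL = result$history),
                   path, row.names = FALSE)
  invisible(path)
}
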