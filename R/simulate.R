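#' Simulate a batch fermentation
#'
#' Integrates either the fundamental 3-state model (when `coupling` is
#' `NULL`; the temperature protocol is then irrelevant) or the 4-state
#' temperature-considered model under a piecewise-constant reference
#' temperature protocol.  Integration uses an adaptive stiff-capable
#' solver (deSolve's `lsoda`) with the model right-hand sides compiled in
#' C; integration is restarted at every protocol breakpoint so the input
#' discontinuity is resolved exactly.
#'
#' Non-negativity of the concentrations is monitored, not projected: any
#' state below `-100 * atol` aborts with an integration error.  For the
#' 4-state model, validity of the linear temperature coupling (adjusted
#' `mu_m` and `alpha` positive) is checked over the reachable temperature
#' range before integrating.
#'
#' @param params A [kinetic_parameters()] object.
#' @param init Initial state: `c(x1, x2, x3)` g/L for the fundamental
#'   model, or `c(x1, x2, x3, x4)` for the temperature-considered model
#'   (x4 defaults to `coupling$theta_0` if absent).
#' @param coupling A [temperature_coupling()] object, or `NULL` for the
#'   fundamental model.
#' @param profile A [temperature_profile()]; required with `coupling`.
#' @param t_end Horizon, h (default 24 h, a full kefir fermentation).
#' @param output_times Requested output grid, h; default 10-min sampling
#'   over `[0, t_end]` (the laboratory acquisition rate).
#' @param rtol,atol Solver tolerances.
#' @param method deSolve integration method.
#' @param compiled Use the C right-hand sides (default); set `FALSE` to
#'   integrate the plain-R [fundamental_rhs()] / [temperature_considered_rhs()]
#'   (slow; used for cross-checking).
#' @return A data frame of class `fermentation_trajectory` with columns
#'   `time_h`, `x1_gL`, `x2_gL`, `x3_gL`, `temp_C`, `ref_temp_C`
#'   (temperature columns are `NA` for the fundamental model), and
#'   attributes `model_tag` (`"fundamental"` or `"temperature_considered"`),
#'   `params`, `coupling`, `profile`.
#' @export
#' @examples
#' tr <- simulate_fermentation(reference_parameters(),
#'                             reference_initial_state(),
#'                             coupling = reference_coupling(),
#'                             profile = make_step_profile(22, 27, 3))
#' tail(tr)
simulate_fermentation <- function(params, init, coupling = NULL,
                                  profile = NULL, t_end = 24,
                                  output_times = NULL,
                                  rtol = 1e-8, atol = 1e-10,
                                  method = "lsoda", compiled = TRUE) {
  check_finite(t_end, "t_end")
  if (t_end <= 0) abort_invalid("t_end must be > 0")
  if (is.null(output_times)) output_times <- seq(0, t_end, by = 1 / 6)
  check_finite(output_times, "output_times")
  if (any(output_times < 0 | output_times > t_end)) {
    abort_invalid("output_times must lie within [0, t_end]")
  }
  output_times <- sort(unique(as.numeric(output_times)))

  if (is.null(coupling)) {
    y0 <- init[1:3]
    sol <- integrate_segment(y0, output_times, params, coupling = NULL,
                             u = NA_real_, rtol, atol, method, compiled)
    out <- data.frame(time_h = sol[, 1],
                      x1_gL = sol[, 2], x2_gL = sol[, 3], x3_gL = sol[, 4],
                      temp_C = NA_real_, ref_temp_C = NA_real_)
    model_tag <- "fundamental"
  } else {
    if (is.null(profile)) {
      abort_invalid("a temperature profile is required for the temperature-considered model")
    }
    y0 <- if (length(init) >= 4L) init[1:4] else c(init[1:3], x4 = coupling$theta_0)
    check_coupling_validity(params, coupling, c(y0[[4]], profile$temps))

    bounds <- unique(c(0, profile$times[profile$times > 0 & profile$times < t_end],
                       t_end))
    rows <- vector("list", length(bounds) - 1L)
    y <- y0
    for (k in seq_len(length(bounds) - 1L)) {
      t_a <- bounds[k]; t_b <- bounds[k + 1L]
      u <- evaluate_profile(profile, t_a)
      inner <- output_times[output_times >= t_a & output_times <= t_b]
      times <- unique(sort(c(t_a, inner, t_b)))
      sol <- integrate_segment(y, times, params, coupling, u,
                               rtol, atol, method, compiled)
      y <- sol[nrow(sol), -1]
      keep <- sol[, 1] %in% inner
      if (k > 1L) keep <- keep & sol[, 1] > t_a  # t_a emitted by previous segment
      rows[[k]] <- sol[keep, , drop = FALSE]
    }
    sol <- do.call(rbind, rows)
    out <- data.frame(time_h = sol[, 1],
                      x1_gL = sol[, 2], x2_gL = sol[, 3], x3_gL = sol[, 4],
                      temp_C = sol[, 5],
                      ref_temp_C = evaluate_profile(profile, sol[, 1]))
    model_tag <- "temperature_considered"
  }

  if (min(out$x1_gL, out$x2_gL, out$x3_gL) < -100 * atol) {
    abort_integration(sprintf(
      "a concentration fell below -100*atol (min %.3e); model left the physical region",
      min(out$x1_gL, out$x2_gL, out$x3_gL)))
  }
  rownames(out) <- NULL
  structure(out, model_tag = model_tag, params = params,
            coupling = coupling, profile = profile,
            rtol = rtol, atol = atol,
            class = c("fermentation_trajectory", "data.frame"))
}

# one deSolve call on [times[1], times[n]] with constant reference u
integrate_segment <- function(y, times, params, coupling, u,
                              rtol, atol, method, compiled) {
  y <- unname(y)
  if (length(times) == 1L) {
    return(matrix(c(times, y), nrow = 1L))
  }
  pv <- as_param_vector(params)
  if (is.null(coupling)) {
    if (compiled) {
      sol <- suppressWarnings(
        deSolve::ode(y = y, times = times, parms = pv,
                     func = "ferm_deriv_fund", dllname = "fermco2",
                     initfunc = "ferm_init_fund",
                     rtol = rtol, atol = atol, method = method))
    } else {
      # raw formula, no argument validation: the solver may probe states
      # with marginally negative concentrations during a step, exactly as
      # the compiled path does
      rhs <- function(t, y, p) {
        phi <- params$mu_m * (1 - y[3] / params$P_i) * y[2] /
          (params$S_m + y[2] + y[2]^2 / params$S_i)
        d1 <- phi * y[1]
        list(c(d1, -d1, (params$alpha * phi + params$beta) * y[1]))
      }
      sol <- suppressWarnings(
        deSolve::ode(y = y, times = times, parms = NULL, func = rhs,
                     rtol = rtol, atol = atol, method = method))
    }
  } else {
    parms <- c(pv, k_mu = coupling$k_mu, k_alpha = coupling$k_alpha,
               theta0 = coupling$theta_0, T_cs = coupling$T_theta_cs, u = u)
    if (compiled) {
      sol <- suppressWarnings(
        deSolve::ode(y = y, times = times, parms = parms,
                     func = "ferm_deriv_temp", dllname = "fermco2",
                     initfunc = "ferm_init_temp",
                     rtol = rtol, atol = atol, method = method))
    } else {
      rhs <- function(t, y, p) {
        mu <- params$mu_m * (1 + coupling$k_mu * (y[4] - coupling$theta_0))
        al <- params$alpha * (1 + coupling$k_alpha * (y[4] - coupling$theta_0))
        phi <- mu * (1 - y[3] / params$P_i) * y[2] /
          (params$S_m + y[2] + y[2]^2 / params$S_i)
        d1 <- phi * y[1]
        list(c(d1, -d1, (al * phi + params$beta) * y[1],
               (u - y[4]) / coupling$T_theta_cs))
      }
      sol <- suppressWarnings(
        deSolve::ode(y = y, times = times, parms = NULL, func = rhs,
                     rtol = rtol, atol = atol, method = method))
    }
  }
  attr_diag <- attributes(sol)$istate
  if (!is.null(attr_diag) && attr_diag[1] < 0) {
    abort_integration(sprintf(
      "ODE solver failed (istate %d) on segment starting t = %g h",
      attr_diag[1], times[1]))
  }
  if (nrow(sol) != length(times)) {
    abort_integration(sprintf(
      "ODE solver returned early (%d of %d requested times) on segment starting t = %g h",
      nrow(sol), length(times), times[1]))
  }
  if (anyNA(sol)) {
    abort_integration(sprintf(
      "ODE solver produced non-finite states on segment starting t = %g h",
      times[1]))
  }
  unclass(sol)
}

# the linear coupling must keep adjusted mu_m and alpha positive over the
# convex hull of reachable temperatures (x4 moves monotonically toward u
# within each segment, so the hull of {x4(0), protocol temps} suffices)
check_coupling_validity <- function(params, coupling, temps) {
  for (th in range(temps)) {
    temperature_adjusted_params(th, params, coupling)
  }
  invisible(TRUE)
}
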