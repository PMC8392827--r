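#' Specific growth rate of the microorganisms
#'
#' Evaluates the growth-rate factor
#' \deqn{\varphi = \mu_m (1 - x_3/P_i)\, x_2 / (S_m + x_2 + x_2^2/S_i),}
#' i.e. Monod-type substrate saturation with substrate inhibition
#' (Haldane/Andrews form) and linear product inhibition.  The product term
#' is applied literally, so \eqn{\varphi} becomes negative once the product
#' exceeds \eqn{P_i} (dying phase); no flooring at zero is done.
#'
#' @param x2 Substrate concentration, g/L (vectorized).
#' @param x3 Product concentration, g/L (vectorized).
#' @param params A [kinetic_parameters()] object.
#' @return Specific growth rate, 1/h.
#' @export
#' @examples
#' growth_rate_factor(0.009, 0.0001, reference_parameters())
growth_rate_factor <- function(x2, x3, params) {
  check_finite(x2, "x2"); check_finite(x3, "x3")
  if (any(x2 < 0)) abort_invalid("substrate concentration x2 must be >= 0")
  params$mu_m * (1 - x3 / params$P_i) * x2 /
    (params$S_m + x2 + x2^2 / params$S_i)
}

#' Right-hand side of the fundamental 3-state model
#'
#' Time derivatives of microorganisms (x1), substrate (x2) and product
#' (x3) in the autonomous constant-temperature model.  The substrate
#' derivative is the exact negative of the growth term, so x1 + x2 is
#' conserved along trajectories.
#'
#' @param state Numeric state vector `c(x1, x2, x3)`, g/L.
#' @param params A [kinetic_parameters()] object.
#' @return Named derivative vector `c(dx1, dx2, dx3)`, g/L/h.
#' @export
#' @examples
#' fundamental_rhs(c(0.0026, 0.009, 0.0001), reference_parameters())
fundamental_rhs <- function(state, params) {
  check_finite(state, "state")
  if (length(state) < 3L) abort_invalid("state must have elements (x1, x2, x3)")
  phi <- growth_rate_factor(state[[2]], state[[3]], params)
  dx1 <- phi * state[[1]]
  c(dx1 = dx1, dx2 = -dx1,
    dx3 = (params$alpha * phi + params$beta) * state[[1]])
}

#' Temperature-adjusted kinetic parameters
#'
#' Linear scaling of the maximum growth rate and the growth-associated
#' yield with the deviation of the bioreactor temperature from the start
#' temperature:
#' \deqn{\mu_{m\vartheta} = \mu_m (1 + k_{\mu m}(x_4 - \vartheta_0)),\quad
#'       \alpha_\vartheta = \alpha (1 + k_\alpha (x_4 - \vartheta_0)).}
#' The linearization is only valid while both adjusted values stay
#' positive; outside that window a range error is raised (no silent
#' clamping, which would corrupt identification objectives).
#'
#' @param x4 Bioreactor temperature, degC.
#' @param params A [kinetic_parameters()] object.
#' @param coupling A [temperature_coupling()] object.
#' @return List with elements `mu_m` and `alpha` (adjusted values).
#' @export
#' @examples
#' temperature_adjusted_params(27, reference_parameters(), reference_coupling())
temperature_adjusted_params <- function(x4, params, coupling) {
  check_finite(x4, "x4")
  dT <- x4 - coupling$theta_0
  mu <- params$mu_m * (1 + coupling$k_mu * dT)
  al <- params$alpha * (1 + coupling$k_alpha * dT)
  if (any(mu <= 0)) {
    abort_range(sprintf(
      "adjusted mu_m is non-positive at x4 = %g degC (linear coupling out of validity)",
      x4[which(mu <= 0)[1]]))
  }
  if (any(al <= 0)) {
    abort_range(sprintf(
      "adjusted alpha is non-positive at x4 = %g degC (linear coupling out of validity)",
      x4[which(al <= 0)[1]]))
  }
  list(mu_m = mu, alpha = al)
}

#' Right-hand side of the temperature-considered 4-state model
#'
#' The fundamental kinetics with `mu_m` and `alpha` replaced by their
#' temperature-adjusted values at the current bioreactor temperature x4,
#' plus a first-order lag of x4 toward the reference temperature `u` of
#' the heating/cooling system: \eqn{\dot x_4 = (u - x_4)/T_{\vartheta cs}}.
#' In the product equation both temperature factors multiply
#' (\eqn{\alpha_\vartheta \mu_{m\vartheta}}), exactly as the model is
#' stated.
#'
#' @param state Numeric state vector `c(x1, x2, x3, x4)`.
#' @param u Reference temperature of the temperature control system, degC.
#' @param params A [kinetic_parameters()] object.
#' @param coupling A [temperature_coupling()] object.
#' @return Named derivative vector `c(dx1, dx2, dx3, dx4)`.
#' @export
#' @examples
#' temperature_considered_rhs(c(0.0026, 0.009, 0.0001, 22), 27,
#'                            reference_parameters(), reference_coupling())
temperature_considered_rhs <- function(state, u, params, coupling) {
  check_finite(state, "state"); check_finite(u, "u")
  if (length(state) < 4L) {
    abort_invalid("state must have elements (x1, x2, x3, x4)")
  }
  adj <- temperature_adjusted_params(state[[4]], params, coupling)
  x2 <- state[[2]]; x3 <- state[[3]]
  if (x2 < 0) abort_invalid("substrate concentration x2 must be >= 0")
  phi <- adj$mu_m * (1 - x3 / params$P_i) * x2 /
    (params$S_m + x2 + x2^2 / params$S_i)
  dx1 <- phi * state[[1]]
  c(dx1 = dx1, dx2 = -dx1,
    dx3 = (adj$alpha * phi + params$beta) * state[[1]],
    dx4 = (u - state[[4]]) / coupling$T_theta_cs)
}
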