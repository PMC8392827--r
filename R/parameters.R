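#' Kinetic parameters of the fundamental fermentation model
#'
#' Bundles the six constants of the 3-state batch-fermentation kinetics:
#' microorganisms grow on the substrate at a specific rate with substrate
#' saturation (`S_m`), substrate inhibition (`S_i`) and product inhibition
#' (`P_i`); dissolved CO2 is produced partly in proportion to growth
#' (`alpha`) and partly growth-independently (`beta`).
#'
#' @param mu_m Maximum specific growth rate of the microorganisms, 1/h.
#' @param P_i Product inhibition constant, g/L: the CO2 concentration at
#'   which the growth term vanishes (above it growth turns negative, the
#'   dying phase).
#' @param S_m Substrate saturation constant, g/L.
#' @param S_i Substrate inhibition constant, g/L.
#' @param alpha Growth-associated product yield, g/L CO2 per g/L biomass
#'   growth (dimensionless).
#' @param beta Growth-independent product formation rate, 1/h.
#' @return An object of class `kinetic_parameters` (named list).
#' @seealso [reference_parameters()] for the identified values of the
#'   studied laboratory bioreactor.
#' @export
#' @examples
#' kinetic_parameters(2.1, 0.75, 0.03, 1.0, 0.38, 0.002)
kinetic_parameters <- function(mu_m, P_i, S_m, S_i, alpha, beta) {
  p <- list(mu_m = mu_m, P_i = P_i, S_m = S_m, S_i = S_i,
            alpha = alpha, beta = beta)
  for (nm in names(p)) {
    v <- p[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0) {
      abort_invalid(sprintf("kinetic parameter '%s' must be a single finite positive number", nm))
    }
  }
  structure(p, class = "kinetic_parameters")
}

#' Temperature-coupling parameters of the 4-state model
#'
#' Constants of the temperature extension: the bioreactor temperature
#' follows a first-order lag (time constant `T_theta_cs`) toward the
#' reference temperature of the heating/cooling system, and the kinetic
#' parameters `mu_m` and `alpha` are scaled linearly with the deviation of
#' the bioreactor temperature from the start temperature `theta_0`.
#'
#' @param k_mu Temperature coefficient on `mu_m`, 1/degC. Zero disables the
#'   coupling of the growth rate.
#' @param k_alpha Temperature coefficient on `alpha`, 1/degC.
#' @param T_theta_cs Time constant of the controlled heating system, h.
#' @param theta_0 Content temperature at fermentation start, degC
#'   (the linearization point; normally the ambient temperature).
#' @return An object of class `temperature_coupling`.
#' @export
#' @examples
#' temperature_coupling(0.14, 0.03, 0.1, 22)
temperature_coupling <- function(k_mu, k_alpha, T_theta_cs, theta_0 = 22) {
  check_finite(k_mu, "k_mu"); check_finite(k_alpha, "k_alpha")
  check_finite(T_theta_cs, "T_theta_cs"); check_finite(theta_0, "theta_0")
  if (length(T_theta_cs) != 1L || T_theta_cs <= 0) {
    abort_invalid("T_theta_cs must be a single positive number (hours)")
  }
  structure(list(k_mu = k_mu, k_alpha = k_alpha,
                 T_theta_cs = T_theta_cs, theta_0 = theta_0),
            class = "temperature_coupling")
}

#' Fermentation state vector
#'
#' @param x1 Microorganisms' concentration, g/L.
#' @param x2 Substrate concentration, g/L.
#' @param x3 Fermentation product (dissolved CO2) concentration, g/L.
#' @param x4 Bioreactor temperature, degC; `NULL` for the 3-state
#'   fundamental model.
#' @return Named numeric vector of length 3 or 4.
#' @export
fermentation_state <- function(x1, x2, x3, x4 = NULL) {
  check_finite(c(x1, x2, x3), "concentrations")
  if (x1 < 0 || x2 < 0 || x3 < 0) {
    abort_invalid("concentrations x1, x2, x3 must be non-negative")
  }
  if (is.null(x4)) return(c(x1 = x1, x2 = x2, x3 = x3))
  check_finite(x4, "x4")
  c(x1 = x1, x2 = x2, x3 = x3, x4 = x4)
}

#' Reference configuration of the studied laboratory bioreactor
#'
#' The identified parameter set for milk fermentation with kefir grains in
#' the studied laboratory batch bioreactor: six kinetic constants, three
#' temperature-coupling constants, and the measured initial loading.
#' Initial concentrations were measured in mg/L (2.6, 9.0, 0.1) and are
#' returned here in the package's canonical unit g/L; the initial
#' temperature is 22 degC.
#'
#' @return `reference_parameters()` a [kinetic_parameters()] object;
#'   `reference_coupling()` a [temperature_coupling()] object;
#'   `reference_initial_state()` a 4-element state vector (g/L, degC).
#' @export
#' @examples
#' reference_parameters()
reference_parameters <- function() {
  kinetic_parameters(mu_m = 2.1, P_i = 0.75, S_m = 0.03, S_i = 1.0,
                     alpha = 0.38, beta = 0.002)
}

#' @rdname reference_parameters
#' @export
reference_coupling <- function() {
  temperature_coupling(k_mu = 0.14, k_alpha = 0.03, T_theta_cs = 0.1,
                       theta_0 = 22)
}

#' @rdname reference_parameters
#' @export
reference_initial_state <- function() {
  fermentation_state(x1 = 0.0026, x2 = 0.009, x3 = 0.0001, x4 = 22)
}

#' @export
print.kinetic_parameters <- function(x, ...) {
  cat("Kinetic parameters (fundamental model):\n")
  cat(sprintf("  mu_m  = %g 1/h     P_i = %g g/L   S_m = %g g/L\n",
              x$mu_m, x$P_i, x$S_m))
  cat(sprintf("  S_i   = %g g/L   alpha = %g       beta = %g 1/h\n",
              x$S_i, x$alpha, x$beta))
  invisible(x)
}

#' @export
print.temperature_coupling <- function(x, ...) {
  cat("Temperature coupling (4-state model):\n")
  cat(sprintf("  k_mu = %g 1/degC  k_alpha = %g 1/degC\n", x$k_mu, x$k_alpha))
  cat(sprintf("  T_theta_cs = %g h  theta_0 = %g degC\n",
              x$T_theta_cs, x$theta_0))
  invisible(x)
}

as_param_vector <- function(params) {
  unlist(params[c("mu_m", "P_i", "S_m", "S_i", "alpha", "beta")])
}
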