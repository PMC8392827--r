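test_that("IAE reproduces closed-form integrals", {
  t <- seq(0, 24, by = 1 / 6)
  expect_identical(iae(rep(0.002, length(t)), rep(0.002, length(t)), t), 0)
  expect_equal(iae(rep(0.002, length(t)), rep(0.001, length(t)), t), 0.024,
               tolerance = 1e-12)
  # trapezoid is exact for a linear integrand
  tt <- seq(0, 1, by = 0.1)
  expect_equal(iae(tt, rep(0, 11), tt), 0.5, tolerance = 1e-12)
})

test_that("IAE validates its grids", {
  expect_error(iae(1:3, 1:4, 1:3), class = "fermco2_invalid_input")
  expect_error(iae(1, 1, 1), class = "fermco2_invalid_input")
  expect_error(iae(1:3, 1:3, c(0, 2, 1)), class = "fermco2_invalid_input")
})

test_that("PSO solves analytic test problems", {
  res <- pso_minimize(function(x) sum(x^2),
                      pso_config(c(-10, -10), c(10, 10), seed = 1))
  expect_lt(res$value, 1e-4)
  res1 <- pso_minimize(function(x) (x - 3)^2, pso_config(0, 10, seed = 2))
  expect_lt(abs(res1$par - 3), 1e-3)
})

test_that("PSO stall rule, history monotonicity and bounds hold", {
  cfg <- pso_config(0, 10, seed = 3)
  res <- pso_minimize(function(x) 5, cfg)
  expect_identical(res$iterations, cfg$stall_iterations)  # flat objective
  expect_identical(res$value, 5)

  res2 <- pso_minimize(function(x) sum((x - c(1, -2))^2) + 0.1 * sum(abs(x)),
                       pso_config(c(-5, -5), c(5, 5), seed = 4))
  expect_true(all(diff(res2$history) <= 0))
  expect_true(all(res2$par >= -5 & res2$par <= 5))
  expect_identical(res2$value, res2$history[res2$iterations])
})

test_that("PSO is reproducible bit-for-bit under a fixed seed", {
  f <- function(x) sum(x^2) + cos(x[1])
  a <- pso_minimize(f, pso_config(c(-4, -4), c(4, 4), seed = 11))
  b <- pso_minimize(f, pso_config(c(-4, -4), c(4, 4), seed = 11))
  expect_identical(a$par, b$par)
  expect_identical(a$history, b$history)
})

test_that("PSO aborts when the objective is mostly non-finite", {
  expect_error(
    pso_minimize(function(x) NaN, pso_config(0, 1, seed = 1)),
    class = "fermco2_optimization_error")
})

test_that("stage preconditions reject the wrong experiment type", {
  expect_error(identify_stage1(ref_step_ds(), ref_init(), seed = 1),
               class = "fermco2_invalid_input")
  expect_error(identify_stage2(ref_const_ds(), reference_parameters(),
                               ref_init(), seed = 1),
               class = "fermco2_invalid_input")
  tiny <- ref_const_ds()[1, , drop = FALSE]
  attr(tiny, "profile") <- attr(ref_const_ds(), "profile")
  class(tiny) <- class(ref_const_ds())
  expect_error(identify_stage1(tiny, ref_init(), seed = 1),
               class = "fermco2_invalid_input")
})

test_that("stage 2 finds no temperature coupling when none was generated", {
  ds0 <- generate_experiment(reference_parameters(),
                             temperature_coupling(0, 0, 0.1, 22),
                             ref_init(), make_step_profile(22, 27, 3),
                             noise_sd = 0)
  s2 <- identify_stage2(ds0, reference_parameters(), ref_init(), seed = 1)
  expect_lt(abs(s2$estimate$k_mu), 0.01)
  expect_lt(abs(s2$estimate$k_alpha), 0.01)
})

test_that("product and substrate inhibition barely move the objective", {
  # the documented weak identifiability of P_i and S_i: a +/-50% change in
  # either moves the IAE far less than the same relative change in mu_m
  ds <- ref_const_ds()
  base <- reference_parameters()
  iae_at <- function(p) {
    tr <- simulate_fermentation(p, ref_init(), output_times = ds$time_h)
    iae(ds$co2_gL, tr$x3_gL, ds$time_h)
  }
  delta <- function(nm, fac) {
    p <- base; p[[nm]] <- base[[nm]] * fac
    iae_at(p)
  }
  d_mu <- max(delta("mu_m", 1.5), delta("mu_m", 0.5))
  for (nm in c("P_i", "S_i")) {
    d <- max(delta(nm, 1.5), delta(nm, 0.5))
    expect_lt(d, 0.05 * d_mu)
  }
})

test_that("two-stage identification wires the stages together", {
  expect_error(identify_two_stage(ref_step_ds(), ref_const_ds(), ref_init(),
                                  seed = 1),
               class = "fermco2_invalid_input")  # swapped datasets

  b1 <- stage1_bounds(); b2 <- stage2_bounds()
  cfg1 <- pso_config(b1$lower, b1$upper, swarm_size = 12,
                     max_iterations = 25L, seed = 9)
  cfg2 <- pso_config(b2$lower, b2$upper, swarm_size = 6,
                     max_iterations = 25L, seed = 9)
  ts <- identify_two_stage(ref_const_ds(), ref_step_ds(), ref_init(),
                           config1 = cfg1, config2 = cfg2)
  expect_s3_class(ts$params, "kinetic_parameters")
  expect_s3_class(ts$coupling, "temperature_coupling")
  expect_true(all(diff(ts$stage1$history) <= 0))
  expect_true(all(diff(ts$stage2$history) <= 0))
  expect_identical(ts$stage1$objective_value,
                   ts$stage1$history[ts$stage1$iterations])
  expect_identical(ts$coupling$theta_0, 22)
})

test_that("identified parameters reproduce the measured CO2 courses", {
  # goodness of fit: the IAE under the estimates is far below 1% of the
  # total CO2 integral of each dataset
  ds <- ref_const_ds()
  s1 <- stage1_run(1)
  tr <- simulate_fermentation(s1$estimate, ref_init(),
                              output_times = ds$time_h)
  total <- iae(ds$co2_gL, rep(0, nrow(ds)), ds$time_h)
  expect_lt(iae(ds$co2_gL, tr$x3_gL, ds$time_h), 0.01 * total)

  ds2 <- ref_step_ds()
  s2 <- stage2_run(1)
  tr2 <- simulate_fermentation(reference_parameters(),
                               c(ref_init(), x4 = 22),
                               coupling = s2$estimate,
                               profile = attr(ds2, "profile"),
                               output_times = ds2$time_h)
  total2 <- iae(ds2$co2_gL, rep(0, nrow(ds2)), ds2$time_h)
  expect_lt(iae(ds2$co2_gL, tr2$x3_gL, ds2$time_h), 0.01 * total2)
})
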