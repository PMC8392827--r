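test_that("step profiles are right-continuous piecewise constants", {
  pr <- make_step_profile(22, 27, 3)
  expect_identical(evaluate_profile(pr, 2.99), 22)
  expect_identical(evaluate_profile(pr, 3), 27)     # right-continuous
  expect_identical(evaluate_profile(pr, 24), 27)
  expect_identical(evaluate_profile(make_step_profile(22, 22, 5), 10), 22)
  expect_identical(evaluate_profile(make_step_profile(22, 27, 0), 1), 27)
  expect_identical(evaluate_profile(temperature_profile(0, 22), 100), 22)
})

test_that("profiles validate their temperature window and times", {
  expect_error(make_step_profile(22, 60, 3), class = "fermco2_range_error")
  expect_error(temperature_profile(c(0, 3, 3), c(22, 25, 27)),
               class = "fermco2_invalid_input")
  expect_error(temperature_profile(c(1, 3), c(22, 27)),
               class = "fermco2_invalid_input")
  expect_error(evaluate_profile(make_constant_profile(22), -1),
               class = "fermco2_range_error")
})

test_that("simulation returns the initial state exactly at t = 0", {
  p <- reference_parameters()
  tr <- simulate_fermentation(p, ref_init(), t_end = 24, output_times = 0)
  expect_identical(tr$x1_gL, 0.0026)
  expect_identical(tr$x2_gL, 0.009)
  expect_identical(tr$x3_gL, 0.0001)
})

test_that("biomass plus substrate is conserved along the trajectory", {
  p <- reference_parameters()
  tr <- simulate_fermentation(p, ref_init())
  expect_lt(max(abs(tr$x1_gL + tr$x2_gL - 0.0116)), 1e-7)
  # and for the 4-state model under a step protocol
  tr4 <- simulate_fermentation(p, reference_initial_state(),
                               coupling = reference_coupling(),
                               profile = make_step_profile(22, 27, 3))
  expect_lt(max(abs(tr4$x1_gL + tr4$x2_gL - 0.0116)), 1e-7)
})

test_that("the 4-state model reduces to the fundamental model", {
  p <- reference_parameters()
  tr3 <- simulate_fermentation(p, ref_init())
  # constant protocol at theta_0: coupling factors stay exactly 1
  tr4 <- simulate_fermentation(p, reference_initial_state(),
                               coupling = reference_coupling(),
                               profile = make_constant_profile(22))
  expect_lt(max(abs(tr4$x3_gL - tr3$x3_gL)), 1e-8)
  # zero coefficients: coupling removed even under a temperature step
  cp0 <- temperature_coupling(0, 0, 0.1, 22)
  tr4z <- simulate_fermentation(p, reference_initial_state(), coupling = cp0,
                                profile = make_step_profile(22, 27, 3))
  expect_lt(max(abs(tr4z$x3_gL - tr3$x3_gL)), 1e-8)
})

test_that("warmer fermentations produce more CO2, pointwise and at 24 h", {
  p <- reference_parameters(); cp <- reference_coupling()
  runs <- lapply(c(20, 22, 24, 26), function(temp) {
    simulate_fermentation(p, c(ref_init(), x4 = temp), coupling = cp,
                          profile = make_constant_profile(temp))
  })
  finals <- vapply(runs, function(tr) tr$x3_gL[nrow(tr)], numeric(1))
  expect_true(all(diff(finals) > 0))
  for (i in 1:3) {
    lo <- runs[[i]]$x3_gL; hi <- runs[[i + 1]]$x3_gL
    sel <- runs[[i]]$time_h > 0
    expect_true(all(hi[sel] >= lo[sel] - 1e-12))
  }
})

test_that("a temperature step accelerates the fermentation from the step on", {
  p <- reference_parameters(); cp <- reference_coupling()
  base <- simulate_fermentation(p, reference_initial_state(), coupling = cp,
                                profile = make_constant_profile(22))
  step3 <- simulate_fermentation(p, reference_initial_state(), coupling = cp,
                                 profile = make_step_profile(22, 27, 3))
  sel <- base$time_h >= 3
  expect_true(all(step3$x3_gL[sel] >= base$x3_gL[sel] - 1e-12))
  expect_gt(step3$x3_gL[nrow(step3)] - base$x3_gL[nrow(base)], 1e-6)
})

test_that("an early step perturbs the CO2 course more than a late one", {
  p <- reference_parameters(); cp <- reference_coupling()
  base <- simulate_fermentation(p, reference_initial_state(), coupling = cp,
                                profile = make_constant_profile(22))
  step3 <- simulate_fermentation(p, reference_initial_state(), coupling = cp,
                                 profile = make_step_profile(22, 27, 3))
  step6 <- simulate_fermentation(p, reference_initial_state(), coupling = cp,
                                 profile = make_step_profile(22, 27, 6))
  d3 <- iae(step3$x3_gL, base$x3_gL, base$time_h)
  d6 <- iae(step6$x3_gL, base$x3_gL, base$time_h)
  expect_gt(d3, d6)
})

test_that("halving the solver tolerances leaves the solution unchanged", {
  p <- reference_parameters()
  a <- simulate_fermentation(p, ref_init(), rtol = 1e-8, atol = 1e-10)
  b <- simulate_fermentation(p, ref_init(), rtol = 5e-9, atol = 5e-11)
  expect_lt(abs(a$x3_gL[nrow(a)] - b$x3_gL[nrow(b)]), 1e-9)
})

test_that("compiled and plain-R right-hand sides integrate identically", {
  p <- reference_parameters(); cp <- reference_coupling()
  grid <- seq(0, 24, by = 2)
  a <- simulate_fermentation(p, ref_init(), output_times = grid)
  b <- simulate_fermentation(p, ref_init(), output_times = grid,
                             compiled = FALSE)
  expect_lt(max(abs(a$x3_gL - b$x3_gL)), 1e-7)
  a4 <- simulate_fermentation(p, reference_initial_state(), coupling = cp,
                              profile = make_step_profile(22, 27, 3),
                              output_times = grid)
  b4 <- simulate_fermentation(p, reference_initial_state(), coupling = cp,
                              profile = make_step_profile(22, 27, 3),
                              output_times = grid, compiled = FALSE)
  expect_lt(max(abs(a4$x3_gL - b4$x3_gL)), 1e-7)
  expect_lt(max(abs(a4$temp_C - b4$temp_C)), 1e-6)
})

test_that("simulation input validation and coupling validity checks fire", {
  p <- reference_parameters()
  expect_error(simulate_fermentation(p, ref_init(), t_end = -1),
               class = "fermco2_invalid_input")
  expect_error(simulate_fermentation(p, ref_init(), output_times = c(0, 30)),
               class = "fermco2_invalid_input")
  expect_error(simulate_fermentation(p, reference_initial_state(),
                                     coupling = reference_coupling()),
               class = "fermco2_invalid_input")  # no profile
  # a large downward step drives adjusted mu_m negative: 22 - 1/0.14 > 14
  cp_strong <- temperature_coupling(0.14, 0.03, 0.1, 22)
  expect_error(
    simulate_fermentation(p, reference_initial_state(), coupling = cp_strong,
                          profile = make_step_profile(22, 14, 3)),
    class = "fermco2_range_error")
})
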