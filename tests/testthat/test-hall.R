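test_that("an individual at equilibrium stays at constant weight", {
  ref <- reference_adult()
  tr <- simulate_weight(ref, 0, horizon = 10)
  expect_lt(max(abs(tr$weight - tr$weight[, 1])), 0.01)
  expect_lt(tr$energy_residual, 1e-3)
})

test_that("equilibrium intake rises with the activity level", {
  lazy <- reference_adult(pal = 1.4)
  active <- reference_adult(pal = 1.8)
  expect_gt(equilibrium_intake(active), equilibrium_intake(lazy))
})

test_that("a sustained deficit converges to the algebraic steady state", {
  ref <- reference_adult()
  tr <- simulate_weight(ref, -100, horizon = 40)
  ss <- steady_state_weight(ref, -100)
  expect_equal(tr$weight[1, 41], ss, tolerance = 1e-3)
  # a permanent -100 kcal/day costs roughly 4-5 kg for a reference adult
  expect_lt(ss - ref$weight, -3.5)
  expect_gt(ss - ref$weight, -5.5)
  # time delay: well under 100% of the change is realised after one year
  frac1 <- (tr$weight[1, 2] - ref$weight) / (ss - ref$weight)
  expect_lt(frac1, 0.9)
  expect_gt(frac1, 0.2)
})

test_that("energy is conserved along the trajectory", {
  set.seed(31)
  ind <- reference_adult()[rep(1, 50), ]
  ind$weight <- rnorm(50, 65, 8); ind$bmi <- ind$weight / ind$height^2
  di <- matrix(rnorm(50 * 5, -40, 60), 50, 5)
  tr <- simulate_weight(ind, di, horizon = 5)
  expect_lt(tr$energy_residual, 1e-3)
})

test_that("the steady state is path independent (step vs ramp)", {
  ref <- reference_adult()
  step <- simulate_weight(ref, -100, horizon = 40)
  ramp_schedule <- c(seq(-20, -100, by = -20), rep(-100, 35))
  ramp <- simulate_weight(ref, ramp_schedule, horizon = 40)
  expect_equal(step$weight[1, 41], ramp$weight[1, 41], tolerance = 1e-3)
})

test_that("larger deficits lose strictly more weight with diminishing annual increments", {
  ref <- reference_adult()
  w100 <- simulate_weight(ref, -100, horizon = 10)$weight[1, ]
  w150 <- simulate_weight(ref, -150, horizon = 10)$weight[1, ]
  expect_true(all(w150[-1] < w100[-1]))
  annual <- diff(w100)
  expect_true(all(diff(abs(annual)) < 0))
})

test_that("the model variant without adaptive thermogenesis reaches a larger steady-state change", {
  ref <- reference_adult()
  ss_at <- steady_state_weight(ref, -100, adaptive = TRUE)
  ss_no <- steady_state_weight(ref, -100, adaptive = FALSE)
  expect_lt(ss_no, ss_at)
  tr_no <- simulate_weight(ref, -100, horizon = 40, adaptive = FALSE)
  expect_equal(tr_no$weight[1, 41], ss_no, tolerance = 1e-3)
})

test_that("infinite or depleting intakes signal errors", {
  ref <- reference_adult()
  expect_error(simulate_weight(ref, NaN, horizon = 2), "finite")
  expect_error(simulate_weight(ref, -2400, horizon = 40), "integration failure")
})
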