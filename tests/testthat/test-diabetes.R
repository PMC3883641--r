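test_that("the hazard multiplier has the documented closed-form limits", {
  par <- hazard_parameters()
  expect_equal(hazard_multiplier(0, c(0, 1, 10, 100), par), rep(1, 4))
  expect_equal(hazard_multiplier(c(-30, 0, 80), 0, par), rep(1, 3))
  expect_equal(hazard_multiplier(100, 1e6, par), 1.45)
  expect_equal(hazard_multiplier(-100, 1e6, par), 1 / 1.45)
  # direct evaluation at one finite time: t = 7.6 years is one mean lag
  expect_equal(hazard_multiplier(-100, 7.6, par),
               exp(log(1 / 1.45) * (1 - exp(-1))), tolerance = 1e-12)
})

test_that("the hazard lag is increasing, concave and saturating in time", {
  par <- hazard_parameters()
  t <- seq(0, 50, by = 0.5)
  lm_ <- abs(log(hazard_multiplier(-100, t, par)))
  expect_true(all(diff(lm_) > 0))
  expect_true(all(diff(diff(lm_)) < 0))
  expect_lt(abs(lm_[length(lm_)] - abs(log(1 / 1.45))), 1e-3)
  # monotone in the glycemic-load change at every time
  m1 <- hazard_multiplier(-50, t[-1], par)
  m2 <- hazard_multiplier(-100, t[-1], par)
  expect_true(all(m2 < m1))
})

test_that("incidence simulation matches the binomial oracle at null exposure", {
  n <- 100000
  inc <- simulate_incidence(0, 307, status0 = rep(FALSE, n), horizon = 10,
                            seed = 21)
  expect_equal(inc$incidence, rep(307, 10)) # expected rate is exact
  py <- sum(inc$at_risk)
  # observed (Bernoulli) rate within 3 binomial SDs over ~1e6 person-years
  rate <- sum(inc$observed * inc$at_risk) / py
  expect_lt(abs(rate - 307), 3 * sqrt(307e-5 * (1 - 307e-5) / py) * 1e5)
})

test_that("a zero baseline produces no cases and diabetes is absorbing", {
  inc0 <- simulate_incidence(0, 0, status0 = rep(FALSE, 100), horizon = 5,
                             seed = 3)
  expect_equal(sum(inc0$cases), 0)
  st0 <- rep(c(TRUE, FALSE), 50)
  inc <- simulate_incidence(-20, 500, status0 = st0, horizon = 20, seed = 4)
  expect_true(all(inc$status[st0]))          # never reverts
  expect_true(all(diff(inc$at_risk) <= 0))   # prevalence non-decreasing
})

test_that("a constant reduction approaches the closed-form incidence ratio", {
  par <- hazard_parameters()
  n <- 20000
  inc <- simulate_incidence(-100, 300, status0 = rep(FALSE, n), horizon = 50,
                            params = par, seed = 6)
  ratio_late <- inc$incidence[50] / 300
  expect_equal(ratio_late, 1 / 1.45, tolerance = 0.01)
})

test_that("probabilities above one are clipped with a warning", {
  expect_warning(
    simulate_incidence(3000, 99000, status0 = rep(FALSE, 50), horizon = 2,
                       seed = 7),
    "clipped"
  )
})

test_that("common random numbers give identical draws across paired calls", {
  n <- 500
  u <- matrix(runif(n * 5), n, 5)
  a <- simulate_incidence(-10, 400, rep(FALSE, n), horizon = 5, u = u)
  b <- simulate_incidence(-10, 400, rep(FALSE, n), horizon = 5, u = u)
  expect_identical(a$status, b$status)
})
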