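test_that("noise-free data return the generating parameters to 1e-4", {
  tr <- deterministic_truth()
  tr$sigma_p <- 0.08 # price variation is needed for identification
  tr$sigma_m <- 0.40
  hh <- generate_households(3000, tr, seed = 2)
  fit <- fit_quaids(hh, base = truth_base(tr))
  expect_true(fit$converged)
  expect_lt(max(abs(fit$params$alpha - tr$params$alpha)), 1e-4)
  expect_lt(max(abs(fit$params$beta - tr$params$beta)), 1e-4)
  expect_lt(max(abs(fit$params$lambda - tr$params$lambda)), 1e-4)
  expect_lt(max(abs(fit$params$gamma - tr$params$gamma)), 1e-4)
})

test_that("constant-share data yield zero gamma, beta and lambda", {
  tr <- deterministic_truth()
  tr$params <- constant_share_params()
  tr$sigma_p <- 0.08
  tr$sigma_m <- 0.40
  hh <- generate_households(3000, tr, seed = 3)
  fit <- fit_quaids(hh, base = truth_base(tr))
  expect_lt(max(abs(fit$params$gamma)), 1e-8)
  expect_lt(max(abs(fit$params$beta)), 1e-8)
  expect_lt(max(abs(fit$params$lambda)), 1e-8)
})

test_that("the homothetic constant-share system has closed-form elasticities", {
  el <- quaids_elasticities(constant_share_params())
  expect_equal(unname(diag(el$e)), rep(-1, 6))
  expect_equal(max(abs(el$e - diag(diag(el$e)))), 0)
  expect_equal(unname(el$eta), rep(1, 6))
})

test_that("fitted systems satisfy adding-up, Cournot aggregation and homogeneity", {
  tr <- default_ground_truth()
  hh <- generate_households(20000, tr, seed = 9)
  fit <- fit_quaids(hh)
  # adding-up at every record, exactly (the outside share is the residual)
  lnp <- matrix(rnorm(60, 0, 0.05), 10, 6); lnp[, 6] <- 0
  w <- quaids_shares(fit$params, lnp, rnorm(10, 0, 0.3))
  expect_equal(unname(rowSums(w)), rep(1, 10), tolerance = 1e-12)

  el <- quaids_elasticities(fit$params)
  cournot <- colSums(el$w * el$e) + el$w
  expect_lt(max(abs(cournot)), 1e-6)
  homog <- rowSums(el$e) + el$eta
  expect_lt(max(abs(homog)), 1e-6)
})

test_that("the two-step estimator recovers elasticities under censoring and noise", {
  tr <- default_ground_truth()
  hh <- generate_households(40000, tr, seed = 10)
  fit <- fit_quaids(hh)
  e_hat <- quaids_elasticities(fit$params)$e[, "ssb"]
  truth <- tr$elasticities_ssb
  # point estimates scatter with SD ~0.01-0.03 at this n
  expect_lt(abs(e_hat[["ssb"]] - truth[["ssb"]]), 0.1)
  # the juice equation is the noisiest (smallest share, 60% censoring)
  expect_lt(abs(e_hat[["juice"]] - truth[["juice"]]), 0.2)
  expect_lt(abs(e_hat[["milk"]] - truth[["milk"]]), 0.05)
  expect_lt(abs(e_hat[["tea"]] - truth[["tea"]]), 0.05)
  # result is invariant to which equation adding-up recovers: the outside
  # coefficients already satisfy the restrictions
  p <- fit$params
  expect_equal(sum(p$alpha), 1, tolerance = 1e-10)
  expect_equal(sum(p$beta), 0, tolerance = 1e-10)
  expect_lt(max(abs(rowSums(p$gamma))), 1e-10)
  expect_equal(p$gamma, t(p$gamma), tolerance = 1e-12)
})

test_that("degenerate inputs are rejected", {
  tr <- default_ground_truth()
  hh <- generate_households(500, tr, seed = 11)
  hh$price_tea <- 0.015
  expect_error(fit_quaids(hh), "no price variation")
})

test_that("bootstrap elasticity intervals bracket the point estimate", {
  tr <- default_ground_truth()
  hh <- generate_households(8000, tr, seed = 12)
  fit <- fit_quaids(hh)
  el <- elasticities(fit, hh, bootstrap = 20, seed = 13)
  tab <- el$table
  expect_true(all(tab$e_ssb_lo <= tab$e_ssb & tab$e_ssb <= tab$e_ssb_hi))
  expect_true(all(tab$eta_lo <= tab$eta & tab$eta <= tab$eta_hi))
  # bootstrap is seed-reproducible
  el2 <- elasticities(fit, hh, bootstrap = 20, seed = 13)
  expect_identical(el$table, el2$table)
})
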