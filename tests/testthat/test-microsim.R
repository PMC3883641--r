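# small-but-real runs: 24 cohorts at modest size keep each run in seconds
small_cfg <- scenario_config(years = 2014:2018)

test_that("a zero tax rate reproduces the baseline exactly (null intervention)", {
  out <- run_scenario(small_cfg, n_per_cohort = 100, seed = 1, tax_rates = 0)
  base <- out[out$scenario == "baseline", -1]
  tax0 <- out[out$scenario == "tax00", -1]
  expect_equal(tax0, base, tolerance = 1e-12)
})

test_that("runs are seed-reproducible and differ across seeds", {
  a <- run_scenario(small_cfg, n_per_cohort = 100, seed = 5)
  b <- run_scenario(small_cfg, n_per_cohort = 100, seed = 5)
  expect_equal(a, b, tolerance = 1e-15)
  c <- run_scenario(small_cfg, n_per_cohort = 100, seed = 6)
  expect_false(isTRUE(all.equal(a$overweight, c$overweight)))
})

test_that("a cohort already entirely overweight stays at prevalence one", {
  cal <- baseline_row("overall")
  cal$overweight_pct <- 99.99
  ind <- generate_individuals(200, "overall", calibration = cal, seed = 2)
  ind$bmi <- pmax(ind$bmi, 28)
  ind$weight <- ind$bmi * ind$height^2
  tr <- simulate_weight(ind, -15, horizon = 5) # a tax-sized deficit
  expect_true(all(tr$weight / ind$height^2 >= 25))
})

test_that("the overweight effect is monotone in the tax rate", {
  out <- run_scenario(small_cfg, n_per_cohort = 400, seed = 3,
                      tax_rates = c(0.1, 0.2, 0.3))
  red <- sapply(c("tax10", "tax20", "tax30"), function(s) {
    contrast_outcomes(out, s)$overweight_reduction_pct
  })
  expect_true(all(diff(red) > 0))
  inc_red <- sapply(c("tax10", "tax20", "tax30"), function(s) {
    contrast_outcomes(out, s)$incidence_reduction_pct
  })
  expect_true(all(diff(inc_red) > 0))
})

test_that("common random numbers shrink the Monte-Carlo variance of contrasts", {
  reds_paired <- reds_unpaired <- numeric(4)
  outs <- lapply(1:5, function(s) {
    run_scenario(small_cfg, n_per_cohort = 150, seed = 10 + s)
  })
  for (k in 1:4) {
    reds_paired[k] <- contrast_outcomes(outs[[k]])$overweight_reduction_pct
    # unpaired: baseline from one replicate, taxed arm from another
    a <- aggregate_outcomes(outs[[k]]); b <- aggregate_outcomes(outs[[k + 1]])
    pb <- a$overweight[a$scenario == "baseline" & a$year == 2018]
    pt <- b$overweight[b$scenario == "tax20" & b$year == 2018]
    reds_unpaired[k] <- 100 * (pb - pt) / pb
  }
  expect_lt(var(reds_paired), var(reds_unpaired))
})

test_that("degenerate uncertainty sampling yields zero-width intervals", {
  unc <- uncertainty_run(small_cfg, n_outer = 2, n_per_cohort = 50, seed = 4,
                         identical_draws = TRUE)
  expect_equal(unc$summary$overweight_reduction_pct_lo,
               unc$summary$overweight_reduction_pct_hi)
  expect_equal(unc$summary$incidence_reduction_pct_lo,
               unc$summary$incidence_reduction_pct_hi)
})

test_that("the uncertainty interval covers the central-parameter contrast", {
  unc <- uncertainty_run(small_cfg, n_outer = 12, n_per_cohort = 150, seed = 7)
  central <- contrast_outcomes(
    run_scenario(small_cfg, n_per_cohort = 150, seed = 7)
  )
  expect_gte(central$overweight_reduction_pct,
             unc$summary$overweight_reduction_pct_lo)
  expect_lte(central$overweight_reduction_pct,
             unc$summary$overweight_reduction_pct_hi)
})

test_that("cases averted behave as bookkeeping requires", {
  out <- run_scenario(small_cfg, n_per_cohort = 150, seed = 8)
  expect_equal(cases_averted(out, population = 0)$overweight_averted, 0)
  null <- run_scenario(small_cfg, n_per_cohort = 150, seed = 8, tax_rates = 0)
  ca0 <- cases_averted(null, scenario = "tax00", population = 1e6)
  expect_equal(ca0$overweight_averted, 0)
  expect_equal(ca0$diabetes_averted, 0)
  ca <- cases_averted(out, population = 550e6)
  expect_gt(ca$overweight_averted, 0)
  expect_gt(ca$diabetes_averted, 0)
  by_age <- cases_averted(out, population = 550e6, by = "age")
  expect_equal(nrow(by_age), 2)
})
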