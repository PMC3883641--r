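BEV <- c("milk", "ssb", "juice", "coffee", "tea")

test_that("the tax shock reproduces the hand-computed kilocalorie changes", {
  e <- ssb_price_elasticities("overall")
  kcal <- setNames(c(207, 46, 34, 21, 82), BEV)
  expect_equal(apply_tax_shock(e, 0, kcal), setNames(rep(0, 5), BEV))
  d <- apply_tax_shock(e, 0.20, kcal)
  expect_equal(d[["ssb"]], -0.94 * 0.20 * 46)        # -8.648
  expect_equal(d[["milk"]], 0.049 * 0.20 * 207)      # +2.029
  expect_equal(sum(d), -2.4, tolerance = 0.05)
  # the glycemic-load consequence of the shock (hand product with the
  # conversion table)
  gl <- sum(kcal_to_glycemic_load(abs(d), BEV) * sign(d))
  expect_equal(gl, -1.0, tolerance = 0.01)
  expect_error(apply_tax_shock(e[-2], 0.2, kcal), "missing elasticity")
  # the floor: consumption cannot go negative even for extreme elasticities
  d2 <- apply_tax_shock(setNames(c(-60, -60, 0, 0, 0), BEV), 0.5, kcal)
  expect_equal(d2[["ssb"]], -46)
})

test_that("linear projection follows the configured growth rule", {
  kcal <- setNames(c(207, 46, 34, 21, 82), BEV)
  p0 <- project_linear(kcal, scenario_config(growth = 0))
  expect_true(all(abs(p0$kcal - rep(kcal, each = 10)) < 1e-12))
  pi_ <- project_linear(kcal, scenario_config(growth = 0.13,
                                              growth_type = "increment"))
  expect_equal(pi_$kcal[pi_$beverage == "ssb" & pi_$year == 2023],
               46 * (1 + 0.13 * 9)) # ~99.8, arithmetic series
  pc <- project_linear(kcal, scenario_config(growth = 0.13,
                                             growth_type = "compound"))
  expect_equal(pc$kcal[pc$beverage == "ssb" & pc$year == 2023],
               46 * 1.13^9) # ~138.3, geometric series
  # non-SSB beverages stay flat
  expect_equal(unique(pi_$kcal[pi_$beverage == "milk"]), 207)
})

test_that("Bass fitting recovers known parameters and its degenerate limits", {
  t_obs <- 2001:2012
  true <- list(m = 60, p = 0.005, q = 0.35)
  s <- ssbtax:::bass_curve(t_obs - 1998, true$m, true$p, true$q)
  fit <- fit_bass(t_obs, s, origin = 1998)
  expect_lt(abs(fit$m - true$m) / true$m, 1e-3)
  expect_lt(abs(fit$p - true$p) / true$p, 1e-3)
  expect_lt(abs(fit$q - true$q) / true$q, 1e-3)
  expect_gt(fit$r_squared, 1 - 1e-10)

  # pure innovation limit: q ~ 0 in truth stays ~ 0 in the fit
  s0 <- ssbtax:::bass_curve(t_obs - 1998, 40, 0.08, 1e-9)
  fit0 <- fit_bass(t_obs, s0, origin = 1998)
  expect_lt(fit0$q, 0.01)
  expect_error(fit_bass(2001:2003, s[1:3]), "at least 4")
})

test_that("Bass calibration reproduces the printed endpoints exactly", {
  bc <- bass_calibrate()
  s <- ssbtax:::bass_curve(c(2014, 2023) - 1998, bc$m, bc$p, bc$q)
  expect_equal(s, c(12.8, 36.3), tolerance = 1e-8)
  # the path is increasing and convex between the endpoints
  path <- ssbtax:::bass_curve(2014:2023 - 1998, bc$m, bc$p, bc$q)
  expect_true(all(diff(path) > 0))
  expect_gt(bc$r_squared, 0.9)
})

test_that("taxed paths fall below baseline for SSBs, monotonically in the tax rate", {
  e <- ssb_price_elasticities("overall")
  kcal <- setNames(c(207, 46, 34, 21, 82), BEV)
  base <- project_linear(kcal, scenario_config())
  expect_equal(taxed_path(base, e, 0)$kcal, base$kcal)
  t10 <- taxed_path(base, e, 0.10)
  t20 <- taxed_path(base, e, 0.20)
  ssb <- function(p) p$kcal[p$beverage == "ssb"]
  expect_true(all(ssb(t10) < ssb(base)))
  expect_true(all(ssb(t20) < ssb(t10)))
  # substitution sign pattern: milk, juice, tea rise; coffee ~ flat
  for (b in c("milk", "juice", "tea")) {
    expect_true(all(t20$kcal[t20$beverage == b] > base$kcal[base$beverage == b]))
  }
  expect_equal(t20$kcal[t20$beverage == "coffee"],
               base$kcal[base$beverage == "coffee"], tolerance = 0.001)
})

test_that("scenario configuration validates its inputs", {
  expect_error(scenario_config(tax_rate = -0.1), "tax_rate")
  expect_error(scenario_config(tax_rate = 0.6), "tax_rate")
  expect_warning(scenario_config(tax_rate = 0.4), "price-variation range")
  expect_silent(scenario_config(tax_rate = 0.30))
  expect_error(scenario_config(years = integer(0)), "horizon")
})
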