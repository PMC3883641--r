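test_that("noise-free records at median prices reproduce the alpha-implied shares exactly", {
  tr <- deterministic_truth()
  hh <- generate_households(10, tr, seed = 1)
  shares <- sapply(c("milk", "ssb", "juice", "coffee", "tea"), function(b) {
    hh[[paste0("q_", b)]] * hh[[paste0("price_", b)]] / hh$total_expenditure
  })
  for (i in 1:5) {
    expect_equal(unname(shares[, i]),
                 rep(unname(tr$params$alpha[i]), 10), tolerance = 1e-12)
  }
})

test_that("expenditure identity holds and output is seed-reproducible", {
  tr <- default_ground_truth()
  hh <- generate_households(2000, tr, seed = 7)
  qcols <- paste0("q_", c("milk", "ssb", "juice", "coffee", "tea"))
  pcols <- paste0("price_", c("milk", "ssb", "juice", "coffee", "tea"))
  expect_equal(hh$beverage_expenditure,
               rowSums(as.matrix(hh[qcols]) * as.matrix(hh[pcols])),
               tolerance = 1e-12)
  expect_identical(hh, generate_households(2000, tr, seed = 7))
  expect_false(identical(hh, generate_households(2000, tr, seed = 8)))
  # SSB prices stay inside the configured variation band around the cohort
  # median
  for (res in c("urban", "rural")) {
    p <- hh$price_ssb[hh$residence == res]
    med <- tr$p_med[["ssb"]] * tr$price_mult[[res]]
    expect_true(all(p >= med / tr$price_band - 1e-9 &
                      p <= med * tr$price_band + 1e-9))
  }
})

test_that("censoring hits the configured zero fraction and is monotone in it", {
  mk_truth <- function(cf) {
    default_ground_truth(censoring = c(milk = 0.1, ssb = cf, juice = 0.6,
                                       coffee = 0.5, tea = 0.1))
  }
  hh <- generate_households(100000, mk_truth(0.30), seed = 1)
  # binomial oracle: sd of the zero fraction is sqrt(.3*.7/1e5) ~ 0.0014
  expect_equal(mean(hh$q_ssb == 0), 0.30, tolerance = 0.01)

  zeros <- sapply(c(0.1, 0.3, 0.5), function(cf) {
    sum(generate_households(20000, mk_truth(cf), seed = 3)$q_ssb == 0)
  })
  expect_true(all(diff(zeros) > 0))
})

test_that("an infeasible parameter set is rejected", {
  tr <- default_ground_truth()
  tr$params$alpha["juice"] <- -0.05 # shares leave [0,1]
  tr$params$alpha["other"] <- tr$params$alpha["other"] + 0.07
  expect_error(generate_households(100, tr, seed = 1), "invalid parameter set")
})
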