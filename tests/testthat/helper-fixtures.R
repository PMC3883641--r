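# Shared fixtures: all synthetic, built in code at test time.

# report every expectation rather than terminating the run at the reporter's
# default failure cap
options(testthat.progress.max_fails = 1000)

# ground truth with all stochastic elements switched off (prices at medians,
# fixed expenditure, no share noise, no censoring)
deterministic_truth <- function() {
  tr <- default_ground_truth(
    share_noise_sd = 0,
    censoring = c(milk = 0, ssb = 0, juice = 0, coffee = 0, tea = 0)
  )
  tr$sigma_p <- 0
  tr$sigma_m <- 0
  tr$price_mult <- c(urban = 1, rural = 1)
  tr
}

truth_base <- function(tr) {
  list(lnp0 = log(tr$p_med), lnm0 = log(tr$m_med))
}

# a reference adult for the energy-balance model
reference_adult <- function(weight = 70, height = 1.65, sex = "M",
                            age_band = "25-44", pal = 1.6) {
  tibble::tibble(
    age_band = age_band, sex = sex, income = "mid", residence = "urban",
    height = height, weight = weight, bmi = weight / height^2,
    diabetes = FALSE, pal = pal
  )
}

# constant-share (homothetic Cobb-Douglas-like) demand parameters
constant_share_params <- function() {
  w <- c(milk = 0.107, ssb = 0.04, juice = 0.02, coffee = 0.018, tea = 0.04)
  w <- c(w, other = 1 - sum(w))
  demand_parameters(alpha = w, beta = rep(0, 6), lambda = rep(0, 6),
                    gamma = matrix(0, 6, 6))
}
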