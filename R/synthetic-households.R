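#' Generate synthetic household beverage-expenditure records
#'
#' Emulates a national consumer-expenditure survey: for each household,
#' log-prices are drawn around cohort medians (truncated to the configured
#' variation band), budget shares are computed from the ground-truth QUAIDS
#' system plus idiosyncratic share noise, and an independent latent-propensity
#' censoring step sets a configurable fraction of purchases to exactly zero
#' per beverage, so the records exhibit the zero-consumption pattern a real
#' expenditure survey shows. Quantities are grams/capita/day, prices
#' constant-rupees per gram.
#'
#' @param n Number of households (>= 1).
#' @param truth An `ssb_ground_truth` object (see [default_ground_truth()]).
#' @param seed Integer seed; identical `(n, truth, seed)` give bit-identical
#'   output.
#' @return A tibble with one row per household: cohort labels, covariates,
#'   per-beverage quantities `q_*` and unit prices `price_*`, total beverage
#'   expenditure and total expenditure (both Rs/capita/day).
#' @export
generate_households <- function(n, truth = default_ground_truth(), seed = 1) {
  stopifnot(n >= 1)
  old <- local_seed(seed)
  on.exit(restore_seed(old), add = TRUE)

  income <- sample(c("low", "mid", "high"), n, replace = TRUE)
  residence <- sample(c("urban", "rural"), n, replace = TRUE,
                      prob = c(truth$urban_share, 1 - truth$urban_share))
  hh_size <- pmax(1L, 1L + stats::rpois(n, 3.2))
  age_head <- round(pmin(90, pmax(18, rnorm(n, 45, 12))))
  availability <- rnorm(n)

  # log-prices around cohort medians, truncated to the +/- band
  band <- log(truth$price_band)
  p_mult <- truth$price_mult[residence]
  lnp <- matrix(0, n, 6, dimnames = list(NULL, GOODS))
  for (b in BEVERAGES) {
    dev <- rnorm(n, 0, truth$sigma_p)
    dev <- pmin(band, pmax(-band, dev))
    lnp[, b] <- dev + log(p_mult)
  }
  lnm <- rnorm(n, 0, truth$sigma_m)

  w <- quaids_shares(truth$params, lnp, lnm)
  if (any(w[, BEVERAGES] < 0) || any(w[, BEVERAGES] > 1)) {
    abort("invalid parameter set: implied budget shares leave [0, 1] at sampled prices")
  }

  if (truth$share_noise_sd > 0) {
    w[, BEVERAGES] <- pmax(
      0, w[, BEVERAGES] + matrix(rnorm(n * 5, 0, truth$share_noise_sd), n, 5)
    )
  }

  # independent latent-propensity censoring: P(purchase) is probit in the
  # availability index, with the intercept chosen so the marginal zero
  # fraction equals the configured censoring fraction exactly
  slope <- truth$censor_slope
  for (b in BEVERAGES) {
    cf <- truth$censoring[[b]]
    if (cf > 0) {
      delta0 <- sqrt(1 + slope^2) * qnorm(1 - cf)
      consume <- rbinom(n, 1L, pnorm(delta0 + slope * availability))
      w[, b] <- w[, b] * consume
    }
  }

  m <- truth$m_med * exp(lnm)
  price <- sweep(exp(lnp[, BEVERAGES, drop = FALSE]), 2,
                 truth$p_med[BEVERAGES], "*")
  qty <- w[, BEVERAGES, drop = FALSE] * m / price

  out <- tibble(
    household_id = seq_len(n),
    income = income,
    residence = residence,
    hh_size = hh_size,
    age_head = age_head,
    availability = availability,
    total_expenditure = m
  )
  for (b in BEVERAGES) {
    out[[paste0("q_", b)]] <- qty[, b]
    out[[paste0("price_", b)]] <- price[, b]
  }
  out$beverage_expenditure <- rowSums(qty * price)
  out
}
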