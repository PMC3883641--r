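#' Quadratic Almost Ideal Demand System parameters
#'
#' Container for the coefficients of a QUAIDS budget-share system over the
#' five beverage classes plus a composite outside good (all non-beverage
#' expenditure, whose price is the numeraire). Budget shares follow
#' \deqn{w_i = \alpha_i + \sum_j \gamma_{ij} \ln p_j + \beta_i z +
#'   \frac{\lambda_i}{b(p)} z^2, \qquad z = \ln\{m / a(p)\},}
#' with the translog price index \eqn{\ln a(p) = \alpha_0 + \sum_i \alpha_i
#' \ln p_i + \tfrac12 \sum_{ij} \gamma_{ij} \ln p_i \ln p_j} and the
#' Cobb-Douglas aggregator \eqn{b(p) = \prod_i p_i^{\beta_i}}. Prices are
#' expressed relative to a base point (by convention the cohort medians), so
#' \eqn{\alpha_0} is fixed at 0 there.
#'
#' @param alpha,beta,lambda Numeric vectors of length 6 (five beverages plus
#'   `other`), satisfying the adding-up restrictions `sum(alpha) == 1`,
#'   `sum(beta) == 0`, `sum(lambda) == 0`.
#' @param gamma Symmetric 6 x 6 price-coefficient matrix with zero row sums
#'   (homogeneity; adding-up across equations follows by symmetry).
#' @param alpha0 Translog price-index intercept (0 at the base point).
#' @return An object of class `ssb_demand_params`.
#' @export
demand_parameters <- function(alpha, beta, lambda, gamma, alpha0 = 0) {
  stopifnot(length(alpha) == 6L, length(beta) == 6L, length(lambda) == 6L,
            is.matrix(gamma), all(dim(gamma) == 6L))
  names(alpha) <- names(beta) <- names(lambda) <- GOODS
  dimnames(gamma) <- list(GOODS, GOODS)
  obj <- structure(
    list(alpha = alpha, beta = beta, lambda = lambda, gamma = gamma,
         alpha0 = alpha0),
    class = "ssb_demand_params"
  )
  validate_demand_parameters(obj)
  obj
}

validate_demand_parameters <- function(params, tol = 1e-6) {
  with(params, {
    if (abs(sum(alpha) - 1) > tol) abort("adding-up violated: sum(alpha) != 1")
    if (abs(sum(beta)) > tol) abort("adding-up violated: sum(beta) != 0")
    if (abs(sum(lambda)) > tol) abort("adding-up violated: sum(lambda) != 0")
    if (max(abs(gamma - t(gamma))) > tol) abort("Slutsky symmetry violated in gamma")
    if (max(abs(rowSums(gamma))) > tol) abort("homogeneity violated: gamma rows must sum to 0")
  })
  invisible(params)
}

#' @export
print.ssb_demand_params <- function(x, ...) {
  cat("QUAIDS demand parameters (5 beverages + outside good)\n")
  cat("  alpha:", format(round(x$alpha, 4)), "\n")
  cat("  beta: ", format(round(x$beta, 4)), "\n")
  cat("  lambda:", format(round(x$lambda, 5)), "\n")
  cat("  gamma (price block, beverages):\n")
  print(round(x$gamma[BEVERAGES, BEVERAGES], 5))
  invisible(x)
}

# Budget shares at log-price matrix lnp (n x 6, outside column 0) and log
# expenditure lnm (length n), both relative to the base point.
quaids_shares <- function(params, lnp, lnm) {
  if (is.null(dim(lnp))) lnp <- matrix(lnp, nrow = 1)
  lna <- params$alpha0 + drop(lnp %*% params$alpha) +
    0.5 * rowSums((lnp %*% params$gamma) * lnp)
  b <- exp(drop(lnp %*% params$beta))
  z <- lnm - lna
  w <- sweep(lnp %*% t(params$gamma), 2, params$alpha, function(g, a) g + a)
  w <- w + outer(z, params$beta) + outer(z^2 / b, params$lambda)
  colnames(w) <- GOODS
  w
}

#' Marshallian and expenditure elasticities of a QUAIDS system at a point
#'
#' Evaluates the standard QUAIDS elasticity formulas at an evaluation point.
#' Marshallian entries `e[i, j]` give the percent change in consumption of
#' good `i` per 1% change in the price of good `j`; `eta` are expenditure
#' elasticities.
#'
#' @param params An `ssb_demand_params` object.
#' @param lnp Length-6 log-price vector relative to the base point (default:
#'   the base point itself, i.e. median prices).
#' @param lnm Log total expenditure relative to the base point.
#' @return List with `e` (6 x 6 matrix), `eta` (length 6) and the budget
#'   shares `w` at the point.
#' @export
quaids_elasticities <- function(params, lnp = rep(0, 6), lnm = 0) {
  w <- drop(quaids_shares(params, matrix(lnp, nrow = 1), lnm))
  if (any(w[BEVERAGES] <= 0) || any(w[BEVERAGES] >= 1)) {
    abort("elasticities undefined: a budget share lies outside (0, 1) at the evaluation point")
  }
  lna <- params$alpha0 + sum(params$alpha * lnp) +
    0.5 * drop(t(lnp) %*% params$gamma %*% lnp)
  b <- exp(sum(params$beta * lnp))
  z <- lnm - lna
  mu <- params$beta + 2 * params$lambda * z / b
  dlna <- params$alpha + drop(params$gamma %*% lnp)
  mu_ij <- params$gamma - outer(mu, dlna) -
    outer(params$lambda, params$beta) * z^2 / b
  e <- sweep(mu_ij, 1, w, "/") - diag(6)
  eta <- mu / w + 1
  dimnames(e) <- list(GOODS, GOODS)
  names(eta) <- names(w) <- GOODS
  list(e = e, eta = eta, w = w)
}

#' Ground-truth data-generating process for synthetic household records
#'
#' Constructs the demand parameters, price/expenditure distributions and
#' censoring process used by [generate_households()]. The QUAIDS coefficients
#' are solved so that, at the base point (median prices, median expenditure),
#' the implied elasticities of each beverage with respect to the SSB price
#' equal the packaged estimates for the chosen cohort. Quantities not pinned
#' down by that column (budget shares, expenditure elasticities, own-price
#' elasticities of the other beverages, beverage-beverage cross terms) take
#' the documented defaults below.
#'
#' @param cohort Column of the packaged elasticity table to calibrate to.
#' @param censoring Named fraction of households reporting zero purchases per
#'   beverage (the survey's zero-consumption censoring).
#' @param share_noise_sd Standard deviation of the idiosyncratic share noise.
#' @param price_band Multiplicative half-band of price variation around the
#'   median (1.175 reproduces the survey's 35% SSB price variation range).
#' @return An object of class `ssb_ground_truth`.
#' @export
default_ground_truth <- function(cohort = "overall",
                                 censoring = c(milk = 0.10, ssb = 0.40,
                                               juice = 0.60, coffee = 0.50,
                                               tea = 0.10),
                                 share_noise_sd = 0.004,
                                 price_band = 1.175) {
  w <- c(milk = 0.107, ssb = 0.040, juice = 0.020, coffee = 0.018,
         tea = 0.040)
  w <- c(w, other = 1 - sum(w))
  eta_bev <- c(milk = 1.05, ssb = 1.40, juice = 1.50, coffee = 1.20, tea = 0.90)
  eta <- c(eta_bev, other = (1 - sum(w[BEVERAGES] * eta_bev)) / w["other"])
  names(eta) <- GOODS
  beta <- w * (eta - 1)

  alpha <- w # z = 0 at the base point
  lambda <- c(milk = 0.002, ssb = -0.001, juice = 0.001, coffee = 0.0005,
              tea = -0.0015)
  lambda <- c(lambda, other = -sum(lambda))

  # price coefficients: SSB column from the packaged table, own-price
  # elasticities of the remaining beverages from the defaults, small direct
  # beverage-beverage substitution terms elsewhere
  e_ssb <- ssb_price_elasticities(cohort)
  own <- c(milk = -0.75, juice = -1.10, coffee = -0.90, tea = -0.65)
  gamma <- matrix(0, 6, 6, dimnames = list(GOODS, GOODS))
  for (i in BEVERAGES) {
    gamma[i, "ssb"] <- w[i] * (e_ssb[i] + (i == "ssb")) + beta[i] * alpha["ssb"]
  }
  for (i in names(own)) {
    gamma[i, i] <- w[i] * (own[i] + 1) + beta[i] * alpha[i]
  }
  cross <- rbind(
    c("milk", "juice", 3e-4), c("milk", "coffee", 2e-4), c("milk", "tea", -8e-4),
    c("juice", "coffee", 1e-4), c("juice", "tea", 2e-4), c("coffee", "tea", 4e-4)
  )
  for (k in seq_len(nrow(cross))) {
    gamma[cross[k, 1], cross[k, 2]] <- as.numeric(cross[k, 3])
  }
  gamma["ssb", ] <- gamma[, "ssb"] # symmetrize the SSB row
  blk <- gamma[BEVERAGES, BEVERAGES]
  blk[lower.tri(blk)] <- t(blk)[lower.tri(blk)]
  gamma[BEVERAGES, BEVERAGES] <- blk
  gamma[BEVERAGES, "other"] <- -rowSums(gamma[BEVERAGES, BEVERAGES])
  gamma["other", BEVERAGES] <- gamma[BEVERAGES, "other"]
  gamma["other", "other"] <- -sum(gamma["other", BEVERAGES])

  params <- demand_parameters(alpha, beta, lambda, gamma)

  censoring <- censoring[BEVERAGES]
  structure(
    list(
      params = params,
      cohort = cohort,
      # medians of the generating distributions (Rs/gram; Rs/capita/day)
      p_med = c(milk = 0.032, ssb = 0.045, juice = 0.060, coffee = 0.040,
                tea = 0.015),
      m_med = 50,
      sigma_p = 0.08,
      sigma_m = 0.40,
      price_band = price_band,
      share_noise_sd = share_noise_sd,
      censoring = censoring,
      censor_slope = 0.30, # probit loading of censoring on the availability index
      urban_share = 0.45,
      # mild systematic price differences between cohorts
      price_mult = c(urban = 1.04, rural = 0.97),
      elasticities_ssb = e_ssb,
      eta = eta
    ),
    class = "ssb_ground_truth"
  )
}

#' @export
print.ssb_ground_truth <- function(x, ...) {
  cat("Ground truth for synthetic household generation (cohort:", x$cohort, ")\n")
  cat("  SSB-price elasticity column:",
      paste(names(x$elasticities_ssb), round(x$elasticities_ssb, 3),
            sep = "=", collapse = ", "), "\n")
  cat("  censoring fractions:",
      paste(names(x$censoring), x$censoring, sep = "=", collapse = ", "), "\n")
  invisible(x)
}
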