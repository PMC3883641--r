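#' First-stage censoring model for one beverage
#'
#' Fits a probit of the purchase indicator (quantity > 0) on household
#' covariates, and returns the fitted purchase probability \eqn{\hat\Phi} and
#' normal density \eqn{\hat\phi} per household. These are the multipliers the
#' two-step censored share system uses: the latent share equation enters the
#' observed-share regression scaled by \eqn{\hat\Phi}, with \eqn{\hat\phi}
#' carrying a free coefficient per equation.
#'
#' @param records Household tibble from [generate_households()] (or same
#'   layout).
#' @param beverage One of `"milk"`, `"ssb"`, `"juice"`, `"coffee"`, `"tea"`.
#' @param covariates Character vector of covariate columns for the probit.
#' @return List with `coefficients`, `Phi`, `phi`, `consuming_fraction` and
#'   the `beverage` label; class `ssb_first_stage`.
#' @export
fit_first_stage <- function(records, beverage,
                            covariates = c("availability", "hh_size",
                                           "age_head")) {
  qcol <- paste0("q_", beverage)
  if (!qcol %in% names(records)) abort(paste0("unknown beverage: ", beverage))
  y <- as.numeric(records[[qcol]] > 0)
  frac <- mean(y)
  X <- cbind(`(Intercept)` = 1,
             as.matrix(records[, covariates, drop = FALSE]))
  storage.mode(X) <- "double"

  if (frac == 1 || frac == 0) {
    # no-censoring (or never-purchased) limit: return the degenerate fit
    if (frac == 0) abort(paste0("degenerate censoring: no household purchases ", beverage))
    eta <- rep(qnorm(1 - 1e-12), nrow(X))
    return(structure(list(
      beverage = beverage, coefficients = NULL,
      Phi = pnorm(eta), phi = dnorm(eta), consuming_fraction = frac
    ), class = "ssb_first_stage"))
  }

  beta <- probit_newton(X, y)
  eta <- drop(X %*% beta)
  structure(list(
    beverage = beverage,
    coefficients = setNames(beta, colnames(X)),
    Phi = pnorm(eta),
    phi = dnorm(eta),
    consuming_fraction = frac
  ), class = "ssb_first_stage")
}

# Newton-Raphson probit MLE. Small and fast (a handful of coefficients over
# up to ~10^5 rows inside the household bootstrap); agreement with
# glm(family = binomial("probit")) is checked in the test suite.
probit_newton <- function(X, y, maxit = 50, tol = 1e-10) {
  beta <- qr.solve(X, qnorm(pmin(pmax(mean(y), 0.02), 0.98)) + 0 * y)
  for (it in seq_len(maxit)) {
    eta <- drop(X %*% beta)
    p <- pnorm(eta)
    p <- pmin(pmax(p, 1e-10), 1 - 1e-10)
    d <- dnorm(eta)
    score <- drop(crossprod(X, d * (y - p) / (p * (1 - p))))
    wgt <- d^2 / (p * (1 - p))
    H <- crossprod(X * sqrt(wgt))
    step <- solve(H, score)
    beta <- beta + step
    if (max(abs(step)) < tol) break
  }
  if (it == maxit && max(abs(step)) > 1e-6) {
    abort("degenerate censoring: probit did not converge (possible complete separation)")
  }
  beta
}

# Assemble shares, log-prices (relative to base medians) and log expenditure
# from a household table.
demand_data <- function(records, base = NULL) {
  price <- as.matrix(records[, paste0("price_", BEVERAGES)])
  qty <- as.matrix(records[, paste0("q_", BEVERAGES)])
  m <- records$total_expenditure
  if (is.null(base)) {
    base <- list(lnp0 = log(apply(price, 2, median)), lnm0 = log(median(m)))
  }
  lnp <- matrix(0, nrow(records), 6, dimnames = list(NULL, GOODS))
  lnp[, BEVERAGES] <- sweep(log(price), 2, base$lnp0, "-")
  w <- qty * price / m
  colnames(w) <- BEVERAGES
  list(w = w, lnp = lnp, lnm = log(m) - base$lnm0, base = base)
}

#' Fit the censored QUAIDS share system
#'
#' Estimates the QUAIDS coefficients from household records by iterated
#' feasible least squares on the stacked beverage share equations, with the
#' two-step censoring correction applied (each equation scaled by the fitted
#' purchase probability, plus a free density term). Slutsky symmetry is
#' imposed directly through the stacked parameterisation; homogeneity and
#' adding-up recover the outside-good coefficients. The composite outside
#' good's share equation is the one dropped; by construction the fitted
#' system satisfies adding-up at every record.
#'
#' @param records Household tibble.
#' @param first_stage Named list of `ssb_first_stage` objects (one per
#'   beverage); fitted internally when `NULL`.
#' @param base Optional list `(lnp0, lnm0)` giving the log price/expenditure
#'   normalisation point; defaults to sample medians.
#' @param start Optional `ssb_demand_params` used as warm start.
#' @param tol,maxit Convergence tolerance on the parameter step and iteration
#'   cap of the outer (price-index) iteration.
#' @return An object of class `ssb_demand_fit`: `params`
#'   (`ssb_demand_params`), `xi` (density-term coefficients), `first_stage`,
#'   `base`, `iterations`, `converged`, `sigma` (residual SDs).
#' @export
fit_quaids <- function(records, first_stage = NULL, base = NULL,
                       start = NULL, tol = 1e-8, maxit = 100) {
  for (b in BEVERAGES) {
    if (sd(records[[paste0("price_", b)]]) <= 0) {
      abort(paste0("no price variation for ", b))
    }
  }
  if (is.null(first_stage)) {
    first_stage <- lapply(setNames(BEVERAGES, BEVERAGES),
                          function(b) fit_first_stage(records, b))
  }
  dat <- demand_data(records, base)
  n <- nrow(dat$w)
  Phi <- vapply(BEVERAGES, function(b) first_stage[[b]]$Phi, numeric(n))
  phi <- vapply(BEVERAGES, function(b) first_stage[[b]]$phi, numeric(n))

  # free parameters: alpha (5), gamma upper triangle incl. diagonal (15),
  # beta (5), lambda (5), xi (5)
  pairs <- which(upper.tri(matrix(0, 5, 5), diag = TRUE), arr.ind = TRUE)
  k_alpha <- 1:5
  k_gamma <- 5 + seq_len(nrow(pairs))
  k_beta <- 20 + 1:5
  k_lambda <- 25 + 1:5
  k_xi <- 30 + 1:5
  npar <- 35

  if (is.null(start)) {
    alpha <- colMeans(dat$w)
    beta <- rep(0, 5); lambda <- rep(0, 5); gam <- matrix(0, 5, 5)
  } else {
    alpha <- start$alpha[BEVERAGES]
    beta <- start$beta[BEVERAGES]
    lambda <- start$lambda[BEVERAGES]
    gam <- start$gamma[BEVERAGES, BEVERAGES]
  }

  lnp <- dat$lnp[, BEVERAGES, drop = FALSE]
  y <- as.vector(dat$w) # stacked by equation
  theta_old <- rep(Inf, npar)
  converged <- FALSE

  for (it in seq_len(maxit)) {
    # price indices at current coefficients (outside good price is numeraire)
    lna <- drop(lnp %*% alpha) + 0.5 * rowSums((lnp %*% gam) * lnp)
    bP <- exp(drop(lnp %*% beta))
    z <- dat$lnm - lna
    q <- z^2 / bP

    X <- matrix(0, 5L * n, npar)
    for (i in 1:5) {
      rows <- (i - 1L) * n + seq_len(n)
      X[rows, k_alpha[i]] <- Phi[, i]
      X[rows, k_beta[i]] <- Phi[, i] * z
      X[rows, k_lambda[i]] <- Phi[, i] * q
      X[rows, k_xi[i]] <- phi[, i]
    }
    for (k in seq_len(nrow(pairs))) {
      i <- pairs[k, 1]; j <- pairs[k, 2]
      rows_i <- (i - 1L) * n + seq_len(n)
      X[rows_i, k_gamma[k]] <- Phi[, i] * lnp[, j]
      if (i != j) {
        rows_j <- (j - 1L) * n + seq_len(n)
        X[rows_j, k_gamma[k]] <- Phi[, j] * lnp[, i]
      }
    }
    fit <- stats::lm.fit(X, y)
    theta <- fit$coefficients
    theta[is.na(theta)] <- 0

    alpha <- theta[k_alpha]
    beta <- theta[k_beta]
    lambda <- theta[k_lambda]
    gam <- matrix(0, 5, 5)
    gam[pairs] <- theta[k_gamma]
    gam[pairs[, c(2, 1)]] <- theta[k_gamma]

    step <- max(abs(theta - theta_old))
    theta_old <- theta
    if (step < tol) { converged <- TRUE; break }
  }
  if (!converged) {
    warn(paste0("QUAIDS iteration stopped after ", maxit,
                " iterations (last step ", signif(step, 3), ")"))
  }

  # recover outside-good coefficients from adding-up / homogeneity / symmetry
  alpha6 <- c(alpha, 1 - sum(alpha))
  beta6 <- c(beta, -sum(beta))
  lambda6 <- c(lambda, -sum(lambda))
  gamma6 <- matrix(0, 6, 6)
  gamma6[1:5, 1:5] <- gam
  gamma6[1:5, 6] <- -rowSums(gam)
  gamma6[6, 1:5] <- gamma6[1:5, 6]
  gamma6[6, 6] <- -sum(gamma6[6, 1:5])

  resid <- matrix(y - fit$fitted.values, n, 5)
  structure(list(
    params = demand_parameters(alpha6, beta6, lambda6, gamma6),
    xi = setNames(theta[k_xi], BEVERAGES),
    first_stage = first_stage,
    base = dat$base,
    iterations = it,
    converged = converged,
    sigma = apply(resid, 2, sd),
    n = n
  ), class = "ssb_demand_fit")
}

#' @export
print.ssb_demand_fit <- function(x, ...) {
  cat("Censored QUAIDS fit on", x$n, "households",
      sprintf("(%d iterations, %s)\n", x$iterations,
              if (x$converged) "converged" else "NOT converged"))
  e <- quaids_elasticities(x$params)
  cat("SSB-price elasticity column at the base point:\n")
  print(round(e$e[BEVERAGES, "ssb"], 4))
  invisible(x)
}

#' Elasticities with bootstrap confidence intervals
#'
#' Evaluates the fitted demand system's Marshallian and expenditure
#' elasticities at the base point (cohort median prices and median
#' expenditure) and attaches 95% confidence intervals from a nonparametric
#' bootstrap over households: each replicate resamples households, refits the
#' first-stage probits and the share system (warm-started at the point
#' estimate), and re-evaluates the elasticities at the original base point.
#'
#' @param fit An `ssb_demand_fit`.
#' @param records The household records the fit was computed from.
#' @param bootstrap Number of bootstrap replicates (0 = point estimates only).
#' @param seed Integer seed for the bootstrap resampling.
#' @return An object of class `ssb_elasticities`: tibble `table` (beverage,
#'   elasticity wrt SSB price, expenditure elasticity, CIs), matrices `e`,
#'   `eta`, the evaluation point, and bootstrap draws.
#' @export
elasticities <- function(fit, records = NULL, bootstrap = 0, seed = 1) {
  pt <- quaids_elasticities(fit$params)
  draws <- NULL
  if (bootstrap > 0) {
    if (is.null(records)) abort("bootstrap requires the household records")
    old <- local_seed(seed)
    on.exit(restore_seed(old), add = TRUE)
    n <- nrow(records)
    draws <- array(NA_real_, c(bootstrap, 6, 2),
                   dimnames = list(NULL, GOODS, c("e_ssb", "eta")))
    for (r in seq_len(bootstrap)) {
      idx <- sample.int(n, n, replace = TRUE)
      rb <- records[idx, ]
      fb <- fit_quaids(rb, base = fit$base, start = fit$params,
                       tol = 1e-7, maxit = 40)
      eb <- quaids_elasticities(fb$params)
      draws[r, , 1] <- eb$e[, "ssb"]
      draws[r, , 2] <- eb$eta
    }
  }
  ci <- function(x) quantile(x, c(0.025, 0.975), names = FALSE)
  tab <- tibble(
    beverage = GOODS,
    e_ssb = pt$e[, "ssb"],
    eta = pt$eta,
    share = pt$w
  )
  if (!is.null(draws)) {
    qs <- apply(draws, c(2, 3), ci)
    tab$e_ssb_lo <- qs[1, , 1]; tab$e_ssb_hi <- qs[2, , 1]
    tab$eta_lo <- qs[1, , 2]; tab$eta_hi <- qs[2, , 2]
  }
  structure(list(
    table = tab, e = pt$e, eta = pt$eta, w = pt$w,
    base = fit$base, draws = draws, bootstrap = bootstrap
  ), class = "ssb_elasticities")
}

#' @export
print.ssb_elasticities <- function(x, ...) {
  cat("Beverage demand elasticities at median prices/expenditure\n")
  print(x$table, n = Inf)
  invisible(x)
}
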