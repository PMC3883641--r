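#' Solve the lognormal BMI distribution from calibration targets
#'
#' The BMI marginal is right-skewed lognormal. Its shape (log-scale SD) is
#' anchored once, from the overall cohort's (mean BMI proxy, overweight
#' prevalence) pair; cohort location parameters are then solved so that
#' P(BMI >= 25) equals each cohort's calibrated prevalence at the common
#' shape.
#'
#' @param prevalence Target overweight prevalence, P(BMI >= 25), in `[0, 1)`.
#' @param sigma Log-scale SD; default solves the overall anchor
#'   (mean 24 kg/m^2, prevalence 0.38).
#' @param mean_bmi,threshold Anchor mean and the overweight BMI threshold.
#' @return List with `meanlog` and `sdlog`.
#' @export
bmi_lognormal <- function(prevalence, sigma = NULL, mean_bmi = 24,
                          threshold = 25) {
  if (prevalence < 0 || prevalence >= 1) {
    abort("calibration error: overweight prevalence must lie in [0, 1)")
  }
  if (is.null(sigma)) {
    # solve (mean, prevalence) jointly at the anchor:
    #   exp(mu + s^2/2) = mean ; (log(th) - mu)/s = qnorm(1 - prev)
    zq <- qnorm(1 - 0.38)
    f <- function(s) log(threshold) - (log(mean_bmi) - s^2 / 2) - zq * s
    sigma <- uniroot(f, c(1e-4, 0.305 / 1))$root
  }
  z <- if (prevalence == 0) qnorm(1 - 1e-12) else qnorm(1 - prevalence)
  list(meanlog = log(threshold) - sigma * z, sdlog = sigma)
}

#' Generate synthetic individual health records
#'
#' Emulates an individual-level migration-study sample: draws the joint
#' distribution of height, weight (through BMI), per-beverage kilocalorie
#' intake, and type 2 diabetes status for one demographic cohort, calibrated
#' so that the cohort marginal means of beverage kcal and the overweight
#' prevalence match the packaged baseline table. BMI and beverage intakes are
#' coupled through a Gaussian copula with configurable rank correlation.
#'
#' @param n Number of individuals.
#' @param cohort Either a margin level (`"overall"`, `"urban"`, `"low"`,
#'   `"25-44"`, ...) or a named list/vector with entries `age`, `sex`,
#'   `income`, `residence` identifying a simulation cell.
#' @param calibration Optional one-row calibration (as from [baseline_row()]
#'   or [cohort_cells()]); derived from `cohort` when `NULL`.
#' @param seed Integer seed (bit-reproducible output).
#' @param rho Rank correlation between BMI and each beverage intake.
#' @param intake_cv Coefficient of variation of individual beverage intake
#'   around the cohort mean (gamma marginals).
#' @param sigma_bmi Optional log-scale BMI SD override.
#' @param diabetes_duration Years of average disease duration used to convert
#'   the calibrated incidence (per 100,000/yr) into a baseline status
#'   prevalence.
#' @return Tibble of `IndividualRecord`s: cohort labels, `height` (m),
#'   `weight` (kg), `bmi`, `kcal_<beverage>` (kcal/day), `diabetes` (logical),
#'   `pal` (physical-activity multiplier).
#' @export
generate_individuals <- function(n, cohort = "overall", calibration = NULL,
                                 seed = 1, rho = 0.2, intake_cv = 0.5,
                                 sigma_bmi = NULL, diabetes_duration = 25) {
  stopifnot(n >= 1)
  labels <- resolve_cohort_labels(cohort)
  if (is.null(calibration)) {
    calibration <- if (is.character(cohort) && length(cohort) == 1L) {
      baseline_row(cohort)
    } else {
      cells <- cohort_cells()
      hit <- cells$age == labels$age & cells$sex == labels$sex &
        cells$income == labels$income & cells$residence == labels$residence
      if (!any(hit)) abort("no calibration row for the requested cohort cell")
      cells[hit, ]
    }
  }
  kcal_mean <- baseline_kcal_vector(calibration)
  prev_ow <- calibration$overweight_pct[1] / 100
  inc_dm <- calibration$diabetes_incidence[1]
  if (inc_dm < 0) abort("calibration error: negative diabetes incidence")

  old <- local_seed(seed)
  on.exit(restore_seed(old), add = TRUE)

  # cohort labels: fixed for a cell; sampled by population share for margins
  struct <- cohort_structure_table()
  share <- function(margin, level) struct$share[struct$margin == margin &
                                                  struct$level == level]
  age <- labels$age %||% sample(c("25-44", "45-65"), n, TRUE,
                                prob = c(share("age", "25-44"),
                                         share("age", "45-65")))
  sex <- labels$sex %||% sample(c("M", "F"), n, TRUE,
                                prob = c(share("sex", "M"), share("sex", "F")))
  income <- labels$income %||% sample(c("low", "mid", "high"), n, TRUE)
  residence <- labels$residence %||%
    sample(c("urban", "rural"), n, TRUE,
           prob = c(share("residence", "urban"), share("residence", "rural")))
  if (length(age) == 1L) age <- rep(age, n)
  if (length(sex) == 1L) sex <- rep(sex, n)
  if (length(income) == 1L) income <- rep(income, n)
  if (length(residence) == 1L) residence <- rep(residence, n)

  # Gaussian copula: BMI latent correlated rho with each beverage latent;
  # beverages mutually correlated 0.1
  k <- length(BEVERAGES)
  R <- matrix(0.1, k + 1, k + 1)
  R[1, ] <- R[, 1] <- rho
  diag(R) <- 1
  L <- chol(R)
  Zlat <- matrix(rnorm(n * (k + 1)), n) %*% L
  U <- pnorm(Zlat)

  bl <- bmi_lognormal(prev_ow, sigma = sigma_bmi)
  # truncate BMI support to [12, 60]
  plo <- stats::plnorm(12, bl$meanlog, bl$sdlog)
  phi_ <- stats::plnorm(60, bl$meanlog, bl$sdlog)
  bmi <- stats::qlnorm(plo + U[, 1] * (phi_ - plo), bl$meanlog, bl$sdlog)

  kcal <- matrix(0, n, k, dimnames = list(NULL, BEVERAGES))
  shape <- 1 / intake_cv^2
  for (j in seq_len(k)) {
    mb <- kcal_mean[j]
    kcal[, j] <- if (mb > 0) stats::qgamma(U[, j + 1], shape, shape / mb) else 0
  }

  height <- ifelse(sex == "M", rnorm(n, 1.65, 0.065), rnorm(n, 1.53, 0.060))
  height <- pmin(2.1, pmax(1.3, height))
  weight <- bmi * height^2

  prev_dm <- min(0.95, inc_dm / 1e5 * diabetes_duration)
  diabetes <- runif(n) < prev_dm
  pal <- pmin(2.2, pmax(1.35, rnorm(n, 1.6, 0.12)))

  out <- tibble(
    age_band = age, sex = sex, income = income, residence = residence,
    height = height, weight = weight, bmi = bmi,
    diabetes = diabetes, pal = pal
  )
  for (b in BEVERAGES) out[[paste0("kcal_", b)]] <- kcal[, b]
  attr(out, "calibration") <- calibration
  out
}

resolve_cohort_labels <- function(cohort) {
  if (is.character(cohort) && length(cohort) == 1L) {
    lv <- cohort
    lab <- list(age = NULL, sex = NULL, income = NULL, residence = NULL)
    if (lv %in% c("25-44", "45-65")) lab$age <- lv
    if (lv %in% c("M", "F")) lab$sex <- lv
    if (lv %in% c("low", "mid", "high")) lab$income <- lv
    if (lv %in% c("urban", "rural")) lab$residence <- lv
    return(lab)
  }
  cohort <- as.list(cohort)
  list(age = cohort$age %||% NULL, sex = cohort$sex %||% NULL,
       income = cohort$income %||% NULL, residence = cohort$residence %||% NULL)
}

#' Calibrated baseline values for the 24 simulation cohorts
#'
#' Builds the full 2 (age) x 2 (sex) x 3 (income) x 2 (residence) design from
#' the packaged margin table. Only margins are published, so cells combine
#' margin effects independently — multiplicatively for beverage kcal and
#' diabetes incidence, additively on the logit scale for overweight
#' prevalence — and are then rescaled so that the population-weighted cell
#' averages reproduce the overall row exactly. Cell population weights are
#' products of the margin shares.
#'
#' @return Tibble with one row per cohort cell: labels, population `weight`,
#'   per-beverage `<b>_kcal` (+ `_se`), `overweight_pct` (+ `_se`),
#'   `diabetes_incidence` (+ `_se`).
#' @export
cohort_cells <- function() {
  tab <- beverage_baseline_table()
  struct <- cohort_structure_table()
  overall <- tab[tab$level == "overall", ]
  grid <- expand.grid(age = c("25-44", "45-65"), sex = c("M", "F"),
                      income = c("low", "mid", "high"),
                      residence = c("urban", "rural"),
                      stringsAsFactors = FALSE)
  margin_of <- c(age = "age", sex = "sex", income = "income",
                 residence = "residence")
  w <- rep(1, nrow(grid))
  for (mcol in names(margin_of)) {
    sh <- setNames(struct$share[struct$margin == mcol],
                   struct$level[struct$margin == mcol])
    w <- w * sh[grid[[mcol]]]
  }
  w <- w / sum(w)

  margin_row <- function(level) tab[tab$level == level, ]
  # multiplicative margin ratios for kcal and incidence, logit offsets for
  # prevalence
  out <- as_tibble(grid)
  out$weight <- as.numeric(w)

  for (col in c(paste0(BEVERAGES, "_kcal"), "diabetes_incidence")) {
    v0 <- overall[[col]]
    val <- rep(v0, nrow(grid))
    for (mcol in names(margin_of)) {
      val <- val * vapply(grid[[mcol]],
                          function(lv) margin_row(lv)[[col]] / v0, 0)
    }
    val <- val * v0 / sum(w * val) # rescale to reproduce the overall mean
    out[[col]] <- val
  }
  logit <- function(p) log(p / (1 - p))
  inv_logit <- function(x) 1 / (1 + exp(-x))
  p0 <- overall$overweight_pct / 100
  off <- rep(logit(p0), nrow(grid))
  for (mcol in names(margin_of)) {
    off <- off + vapply(grid[[mcol]], function(lv) {
      logit(margin_row(lv)$overweight_pct / 100) - logit(p0)
    }, 0)
  }
  shift <- uniroot(function(d) sum(w * inv_logit(off + d)) - p0,
                   c(-5, 5), tol = 1e-12)$root
  out$overweight_pct <- 100 * inv_logit(off + shift)

  # cell SEs: the overall row's relative SE applied to each cell value
  out$overweight_se <- overall$overweight_se *
    out$overweight_pct / overall$overweight_pct
  out$diabetes_se <- overall$diabetes_se *
    out$diabetes_incidence / overall$diabetes_incidence
  for (b in BEVERAGES) {
    out[[paste0(b, "_se")]] <- overall[[paste0(b, "_se")]] *
      out[[paste0(b, "_kcal")]] / overall[[paste0(b, "_kcal")]]
  }
  out
}
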