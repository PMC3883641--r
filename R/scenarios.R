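#' Scenario configuration
#'
#' Settings of one policy experiment: tax rate, baseline consumption trend,
#' and horizon. The default reproduces the headline experiment: a 20% excise
#' tax from the start of 2014, against a baseline in which SSB consumption
#' rises by 13% of its 2014 level per year (constant annual increments) and
#' the other beverages stay flat.
#'
#' @param tax_rate Excise tax rate passed fully into the consumer price
#'   (fraction in `[0, 0.5]`; values above 0.35 exceed the price-variation
#'   range that identified the elasticities and trigger a warning).
#' @param trend `"linear"` (constant annual increments) or `"bass"`
#'   (diffusion-model path).
#' @param years Simulation horizon (calendar years).
#' @param growth Annual SSB growth under the linear trend, as a fraction of
#'   the first-year level.
#' @param growth_type `"increment"`: the yearly increase is `growth` times
#'   the first-year level; `"compound"`: year-on-year compounding.
#' @param bass_anchors Named numeric vector of per-capita consumption
#'   anchors (litres/person/year by calendar year) through which the Bass
#'   path is calibrated.
#' @param bass_origin Year the diffusion clock starts.
#' @param nonbev_trend Secular change in non-beverage calorie intake
#'   (kcal/day added per year; food-balance-sheet style drift).
#' @param nonbev_gl_per_kcal Glycemic load per non-beverage kcal (mixed
#'   Indian diet).
#' @return An object of class `ssb_scenario_config`.
#' @export
scenario_config <- function(tax_rate = 0.20, trend = c("linear", "bass"),
                            years = 2014:2023, growth = 0.13,
                            growth_type = c("increment", "compound"),
                            bass_anchors = c("2012" = 11, "2014" = 12.8,
                                             "2023" = 36.3),
                            bass_origin = 1998,
                            nonbev_trend = 8,
                            nonbev_gl_per_kcal = 0.12) {
  trend <- match.arg(trend)
  growth_type <- match.arg(growth_type)
  if (tax_rate < 0 || tax_rate > 0.5) abort("tax_rate must lie in [0, 0.5]")
  if (tax_rate > 0.35) {
    warn("tax_rate exceeds the observed price-variation range (35%); elasticities are extrapolated")
  }
  if (length(years) < 1) abort("horizon must cover at least one year")
  if (growth < 0) abort("growth must be >= 0")
  structure(list(
    tax_rate = tax_rate, trend = trend, years = as.integer(years),
    growth = growth, growth_type = growth_type,
    bass_anchors = bass_anchors, bass_origin = bass_origin,
    nonbev_trend = nonbev_trend, nonbev_gl_per_kcal = nonbev_gl_per_kcal
  ), class = "ssb_scenario_config")
}

#' @export
print.ssb_scenario_config <- function(x, ...) {
  cat(sprintf("Scenario: %d%% SSB tax, %s baseline, %d-%d\n",
              round(100 * x$tax_rate), x$trend, min(x$years), max(x$years)))
  invisible(x)
}

#' Per-beverage kilocalorie change from an SSB price shock
#'
#' The first-order tax conversion: for each beverage, the change in daily
#' kilocalorie intake is its elasticity to the SSB price, times the percent
#' price change, times baseline intake:
#' \eqn{\Delta kcal_b = e_{b,SSB} \times 100\tau \times kcal_b / 100}.
#' Consumption is floored at zero.
#'
#' @param elasticities Named vector of per-beverage elasticities with respect
#'   to the SSB price (e.g. [ssb_price_elasticities()]).
#' @param tax_rate Price change as a fraction (0.20 = a 20% tax fully passed
#'   through).
#' @param baseline_kcal Named per-beverage baseline kcal/day.
#' @return Named vector of kcal/day changes.
#' @export
apply_tax_shock <- function(elasticities, tax_rate, baseline_kcal) {
  if (tax_rate < 0) abort("tax_rate must be >= 0")
  if (any(baseline_kcal < 0)) abort("baseline kcal must be >= 0")
  b <- names(baseline_kcal)
  if (is.null(b)) abort("baseline_kcal must be a named vector")
  if (!all(b %in% names(elasticities))) {
    abort(paste0("missing elasticity entry for: ",
                 paste(setdiff(b, names(elasticities)), collapse = ", ")))
  }
  delta <- unname(elasticities[b]) * tax_rate * baseline_kcal
  pmax(delta, -baseline_kcal) # consumption cannot go negative
}

#' Baseline consumption path under the linear trend
#'
#' SSB kilocalories follow the configured secular rise; the other beverages
#' are held flat (their historical trends are not distinguishable from zero).
#'
#' @param baseline_kcal Named per-beverage kcal/day in the first year.
#' @param config An `ssb_scenario_config` (its `growth`, `growth_type` and
#'   `years` are used).
#' @return Tibble (`year`, `beverage`, `kcal`) of class amenable to
#'   [taxed_path()]; attribute `"scenario"` set to `"baseline"`.
#' @export
project_linear <- function(baseline_kcal, config = scenario_config()) {
  years <- config$years
  y <- seq_along(years) - 1
  mult <- if (config$growth_type == "increment") {
    1 + config$growth * y
  } else {
    (1 + config$growth)^y
  }
  path_tbl(baseline_kcal, years, ssb_mult = mult, scenario = "baseline")
}

#' Baseline consumption path under the Bass diffusion trend
#'
#' SSB kilocalories follow a Bass diffusion curve calibrated through the
#' configured per-capita consumption anchors (litres/person/year), rescaled
#' to the cohort's first-year kilocalorie level.
#'
#' @inheritParams project_linear
#' @return As [project_linear()]; the calibrated `(m, p, q)` are attached as
#'   attribute `"bass"`.
#' @export
project_bass <- function(baseline_kcal, config = scenario_config(trend = "bass")) {
  fitb <- bass_calibrate(config$bass_anchors, origin = config$bass_origin)
  years <- config$years
  s <- bass_curve(years - config$bass_origin, fitb$m, fitb$p, fitb$q)
  mult <- s / s[1]
  out <- path_tbl(baseline_kcal, years, ssb_mult = mult, scenario = "baseline")
  attr(out, "bass") <- fitb
  out
}

path_tbl <- function(baseline_kcal, years, ssb_mult, scenario) {
  stopifnot(length(ssb_mult) == length(years))
  kc <- outer(rep(1, length(years)), baseline_kcal[BEVERAGES])
  kc[, "ssb"] <- baseline_kcal[["ssb"]] * ssb_mult
  out <- tibble(
    year = rep(years, times = length(BEVERAGES)),
    beverage = rep(BEVERAGES, each = length(years)),
    kcal = as.vector(kc)
  )
  attr(out, "scenario") <- scenario
  out
}

#' Taxed counterfactual of a baseline consumption path
#'
#' Applies the elasticity-driven kilocalorie shock of [apply_tax_shock()] to
#' every year of the baseline path from the tax start onward, so substitution
#' effects (milk, juice, tea up; coffee flat) are included every year.
#'
#' @param baseline A path from [project_linear()]/[project_bass()].
#' @param elasticities Named per-beverage elasticities wrt the SSB price.
#' @param tax_rate Fraction; 0 returns the baseline unchanged.
#' @param start_year First taxed year (default: the path's first year).
#' @return Tibble like `baseline` with taxed kcal; attribute `"scenario"` set
#'   to `"tax"`.
#' @export
taxed_path <- function(baseline, elasticities, tax_rate, start_year = NULL) {
  start_year <- start_year %||% min(baseline$year)
  wide <- tidyr::pivot_wider(baseline, names_from = "beverage",
                             values_from = "kcal")
  for (r in seq_len(nrow(wide))) {
    if (wide$year[r] >= start_year) {
      base <- unlist(wide[r, BEVERAGES])
      wide[r, BEVERAGES] <- as.list(base +
        apply_tax_shock(elasticities, tax_rate, base))
    }
  }
  out <- tidyr::pivot_longer(wide, -"year", names_to = "beverage",
                             values_to = "kcal")
  out <- out[order(match(out$beverage, BEVERAGES), out$year), ]
  attr(out, "scenario") <- "tax"
  out
}

#' Attach glycemic load to a consumption path
#'
#' @param path Consumption path tibble (`year`, `beverage`, `kcal`).
#' @param gl_factor Optional named glycemic-load factors (g/kcal); defaults
#'   to the packaged table.
#' @return The path with a `gl` column (g/day).
#' @export
path_glycemic_load <- function(path, gl_factor = NULL) {
  tab <- nutrient_table()
  if (is.null(gl_factor)) gl_factor <- setNames(tab$gl_per_kcal, tab$beverage)
  path$gl <- kcal_to_glycemic_load(path$kcal, path$beverage, factor = gl_factor)
  path
}

# ---- Bass diffusion -------------------------------------------------------

# cumulative-adoption Bass curve: consumption at time t (years since origin)
bass_curve <- function(t, m, p, q) {
  e <- exp(-(p + q) * t)
  m * (1 - e) / (1 + (q / p) * e)
}

#' Fit a Bass diffusion model to an annual consumption series
#'
#' Least-squares fit of the cumulative-adoption Bass curve
#' \eqn{S(t) = m (1 - e^{-(p+q)t}) / (1 + (q/p) e^{-(p+q)t})} by Nelder-Mead
#' on log-transformed parameters.
#'
#' @param year,value The series (>= 4 increasing observations).
#' @param origin Year the diffusion clock starts.
#' @param start Optional starting values `c(m, p, q)`.
#' @return List with `m`, `p`, `q`, `r_squared`, `fitted`, `converged`.
#' @export
fit_bass <- function(year, value, origin = min(year) - 1, start = NULL) {
  if (length(year) < 4) abort("Bass fit requires at least 4 observations")
  bass_lsq(year, value, origin, start)
}

bass_lsq <- function(year, value, origin, start = NULL) {
  t <- year - origin
  if (any(value <= 0)) abort("Bass fit requires positive consumption values")
  start <- start %||% c(m = max(value) * 3, p = 0.01, q = 0.3)
  obj <- function(lp) {
    s <- bass_curve(t, exp(lp[1]), exp(lp[2]), exp(lp[3]))
    sum((s - value)^2)
  }
  opt <- optim(log(start), obj, method = "Nelder-Mead",
               control = list(maxit = 5000, reltol = 1e-14))
  opt2 <- optim(opt$par, obj, method = "Nelder-Mead",
                control = list(maxit = 5000, reltol = 1e-14))
  if (opt2$convergence != 0) {
    abort(paste0("Bass fit did not converge (objective ",
                 signif(opt2$value, 4), ")"))
  }
  par <- exp(opt2$par)
  fitted <- bass_curve(t, par[1], par[2], par[3])
  r2 <- 1 - sum((value - fitted)^2) / sum((value - mean(value))^2)
  list(m = unname(par[1]), p = unname(par[2]), q = unname(par[3]),
       r_squared = r2, fitted = fitted, converged = TRUE)
}

#' Calibrate a Bass curve through printed consumption anchors
#'
#' Solves `(m, p, q)` so the diffusion curve passes through the final two
#' anchors (the projection endpoints) exactly, while fitting any earlier
#' historical anchors in least squares: for a candidate imitation rate `q`,
#' the innovation rate `p` is root-solved so the curve's endpoint ratio is
#' matched and the scale `m` pinned by the first endpoint; `q` is then chosen
#' to minimise the residual at the remaining anchors. (The printed historical
#' level and the two printed endpoints are not jointly representable by one
#' Bass curve, so the endpoints take priority.)
#'
#' @param anchors Named numeric vector, names = calendar years (increasing).
#' @param origin Diffusion start year.
#' @return List with `m`, `p`, `q`, `fitted` (at the anchors), `r_squared`;
#'   errors if the endpoints cannot be reproduced to within 1e-8 relative.
#' @export
bass_calibrate <- function(anchors = c("2012" = 11, "2014" = 12.8,
                                       "2023" = 36.3), origin = 1998) {
  yrs <- as.numeric(names(anchors))
  val <- as.numeric(anchors)
  o <- order(yrs); yrs <- yrs[o]; val <- val[o]
  nk <- length(yrs)
  if (nk < 2) abort("Bass calibration needs at least two anchors")
  t1 <- yrs[nk - 1] - origin; t2 <- yrs[nk] - origin
  s1 <- val[nk - 1]; s2 <- val[nk]
  r0 <- s2 / s1

  solve_p <- function(q) {
    g <- function(lp) {
      p <- exp(lp)
      bass_curve(t2, 1, p, q) / bass_curve(t1, 1, p, q) - r0
    }
    lo <- -35; hi <- log(q) - 1e-9
    if (g(lo) < 0 || g(hi) > 0) return(NA_real_)
    exp(uniroot(g, c(lo, hi), tol = 1e-14)$root)
  }
  eval_q <- function(lq) {
    q <- exp(lq)
    p <- solve_p(q)
    if (is.na(p)) return(list(sse = 1e10)) # infeasible q: large finite penalty
    m <- s1 / bass_curve(t1, 1, p, q)
    sse <- if (nk > 2) {
      sum((bass_curve(yrs[1:(nk - 2)] - origin, m, p, q) - val[1:(nk - 2)])^2)
    } else 0
    list(sse = sse, m = m, p = p, q = q)
  }
  opt <- optim(log(0.12), function(lq) eval_q(lq)$sse, method = "Brent",
               lower = log(1e-3), upper = log(2))
  sol <- eval_q(opt$par)
  if (!is.finite(sol$sse) || sol$sse >= 1e10) {
    abort("Bass calibration failed: no feasible (p, q)")
  }
  fitted <- bass_curve(yrs - origin, sol$m, sol$p, sol$q)
  if (max(abs(fitted[(nk - 1):nk] - c(s1, s2)) / c(s1, s2)) > 1e-8) {
    abort("Bass calibration failed to reproduce the endpoints")
  }
  r2 <- if (nk > 2) 1 - sum((val - fitted)^2) / sum((val - mean(val))^2) else 1
  list(m = sol$m, p = sol$p, q = sol$q, fitted = fitted, r_squared = r2)
}
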