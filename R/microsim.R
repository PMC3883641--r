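#' Central parameter bundle for the microsimulation
#'
#' Collects every model input the simulation consumes: cohort-cell
#' calibration, the elasticity table, glycemic-load factors, Hall
#' energy-balance parameters and diabetes hazard parameters. The uncertainty
#' loop perturbs a bundle via [draw_parameter_bundle()]; the central bundle
#' carries all point estimates.
#'
#' @return List of class `ssb_bundle`.
#' @export
parameter_bundle <- function() {
  nt <- nutrient_table()
  structure(list(
    cells = cohort_cells(),
    elasticities = elasticity_table(),
    gl_factor = setNames(nt$gl_per_kcal, nt$beverage),
    hall = hall_parameters(),
    hazard = hazard_parameters()
  ), class = "ssb_bundle")
}

#' Sample a parameter bundle from the input uncertainty distributions
#'
#' Every model parameter reported with a confidence interval or standard
#' error is drawn from a normal distribution implied by it (SD = CI width /
#' 3.92 where only a 95% CI is printed), truncated where a sign is
#' constrained: the elasticity column (one study-level z-score per beverage,
#' shared across cohorts), glycemic-load factors, beverage kcal calibration,
#' overweight prevalence (logit scale), diabetes baseline incidence (log
#' scale), the diabetes RR and effect rate, and the Hall parameters carrying
#' standard errors.
#'
#' @param seed Integer seed for the draw.
#' @return A perturbed `ssb_bundle`.
#' @export
draw_parameter_bundle <- function(seed) {
  old <- local_seed(seed)
  on.exit(restore_seed(old), add = TRUE)
  b <- parameter_bundle()

  # elasticities: common z per beverage applied to every cohort column
  z <- setNames(rnorm(length(BEVERAGES)), BEVERAGES)
  el <- b$elasticities
  se <- (el$hi - el$lo) / 3.92
  el$estimate <- el$estimate + z[el$beverage] * se
  b$elasticities <- el

  # glycemic load per kcal, truncated positive
  nt <- nutrient_table()
  glse <- (nt$gl_hi - nt$gl_lo) / 3.92
  b$gl_factor <- setNames(pmax(1e-4, rnorm(5, nt$gl_per_kcal, glse)),
                          nt$beverage)

  # calibration: study-level shifts applied to all cells coherently
  overall <- baseline_row("overall")
  cells <- b$cells
  for (bev in BEVERAGES) {
    rel <- rnorm(1, 1, overall[[paste0(bev, "_se")]] /
                   overall[[paste0(bev, "_kcal")]])
    cells[[paste0(bev, "_kcal")]] <- cells[[paste0(bev, "_kcal")]] * max(rel, 0.2)
  }
  zp <- rnorm(1)
  lo_ <- function(p) log(p / (1 - p))
  p0 <- overall$overweight_pct / 100
  shift <- lo_(min(0.99, max(0.01, p0 + zp * overall$overweight_se / 100))) -
    lo_(p0)
  pc <- pmin(0.99, pmax(1e-4, cells$overweight_pct / 100))
  cells$overweight_pct <- 100 / (1 + exp(-(lo_(pc) + shift)))
  zi <- rnorm(1)
  inc_rel <- exp(zi * overall$diabetes_se / overall$diabetes_incidence)
  cells$diabetes_incidence <- cells$diabetes_incidence * inc_rel
  b$cells <- cells

  # Hall parameters with nonzero SE
  ht <- hall_parameter_table()
  hdraw <- list()
  for (i in seq_len(nrow(ht))) {
    if (ht$se[i] > 0) {
      hdraw[[ht$parameter[i]]] <- max(0.05 * ht$value[i],
                                      rnorm(1, ht$value[i], ht$se[i]))
    }
  }
  b$hall <- do.call(hall_parameters, hdraw)

  # hazard: RR and effect rate
  hz <- hazard_parameters()
  rr <- max(1.01, rnorm(1, hz$rr, diff(hz$rr_ci) / 3.92))
  er <- max(0.01, rnorm(1, hz$effect_rate, diff(hz$effect_rate_ci) / 3.92))
  b$hazard <- hazard_parameters(rr = rr, effect_rate = er)
  b
}

# elasticity column for one cohort cell: average of its income-margin and
# residence-margin columns
cell_elasticities <- function(elast_table, income, residence) {
  e1 <- elast_table[elast_table$cohort == income, ]
  e2 <- elast_table[elast_table$cohort == residence, ]
  v1 <- setNames(e1$estimate, e1$beverage)[BEVERAGES]
  v2 <- setNames(e2$estimate, e2$beverage)[BEVERAGES]
  (v1 + v2) / 2
}

#' Run one paired microsimulation (baseline plus taxed counterfactuals)
#'
#' Simulates the 24 demographic cohorts over the configured horizon: for
#' each cohort, individuals are sampled from the calibrated joint
#' distribution, the cohort consumption path is projected (linear or Bass
#' baseline), tax counterfactuals apply the elasticity-driven kilocalorie
#' shock from the tax start onward, and each individual's intake change
#' drives the energy-balance weight model while the glycemic-load change
#' drives the diabetes hazard. Baseline and taxed arms share individuals and
#' random numbers (common random numbers), so contrasts are free of
#' between-arm sampling noise.
#'
#' @param config [scenario_config()].
#' @param n_per_cohort Individuals per cohort cell.
#' @param seed Integer seed (drives individual sampling and disease shocks).
#' @param tax_rates Tax rates to simulate against the shared baseline
#'   (default: the config's rate).
#' @param bundle Parameter bundle (central estimates by default).
#' @return `ssb_outcomes`: tidy tibble with scenario, cohort labels, cell
#'   weight, year, overweight prevalence (fraction BMI >= 25), diabetes
#'   incidence per 100,000 (expected, at-risk denominator), observed
#'   incidence, and mean beverage kcal/day.
#' @export
run_scenario <- function(config = scenario_config(), n_per_cohort = 2000,
                         seed = 1, tax_rates = config$tax_rate,
                         bundle = parameter_bundle()) {
  cells <- bundle$cells
  years <- config$years
  horizon <- length(years)
  n_cells <- nrow(cells)

  # sample all cohorts once (scenario-independent)
  inds <- vector("list", n_cells)
  for (c in seq_len(n_cells)) {
    inds[[c]] <- generate_individuals(
      n_per_cohort, cohort = as.list(cells[c, c("age", "sex", "income",
                                                "residence")]),
      calibration = cells[c, ], seed = child_seed(seed, c)
    )
  }
  pop <- dplyr::bind_rows(inds)
  cell_of <- rep(seq_len(n_cells), each = n_per_cohort)
  kcal_ind <- as.matrix(pop[, paste0("kcal_", BEVERAGES)])

  # common random numbers for diabetes transitions
  old <- local_seed(child_seed(seed, 1000))
  u <- matrix(runif(nrow(pop) * horizon), nrow(pop), horizon)
  restore_seed(old)

  scen_names <- c("baseline", sprintf("tax%02d", round(100 * tax_rates)))
  out_rows <- list()

  # cohort-level baseline paths (kcal multipliers per beverage-year)
  base_paths <- vector("list", n_cells)
  for (c in seq_len(n_cells)) {
    kc <- baseline_kcal_vector(cells[c, ])
    base_paths[[c]] <- if (config$trend == "linear") {
      project_linear(kc, config)
    } else {
      project_bass(kc, config)
    }
  }

  for (s in seq_along(scen_names)) {
    scen <- scen_names[s]
    tau <- if (scen == "baseline") 0 else tax_rates[s - 1]

    # per-individual intake and glycemic-load changes vs the pre-period
    di <- matrix(0, nrow(pop), horizon)
    dgl <- matrix(0, nrow(pop), horizon)
    kcal_mean_cell <- matrix(0, n_cells, horizon)
    ratio_store <- vector("list", n_cells)
    for (c in seq_len(n_cells)) {
      kc <- baseline_kcal_vector(cells[c, ])
      path <- base_paths[[c]]
      if (tau > 0) {
        e_c <- cell_elasticities(bundle$elasticities, cells$income[c],
                                 cells$residence[c])
        path <- taxed_path(path, e_c, tau, start_year = min(years))
      }
      wide <- tidyr::pivot_wider(path, names_from = "beverage",
                                 values_from = "kcal")
      wide <- wide[order(wide$year), ]
      ratio <- sweep(as.matrix(wide[, BEVERAGES]), 2, pmax(kc, 1e-9), "/")
      ratio[, kc == 0] <- 1
      ratio_store[[c]] <- ratio
      rows <- which(cell_of == c)
      kb <- kcal_ind[rows, , drop = FALSE]
      di[rows, ] <- kb %*% (t(ratio) - 1)
      dgl[rows, ] <- (kb * rep(bundle$gl_factor[BEVERAGES],
                               each = length(rows))) %*% (t(ratio) - 1)
      kcal_mean_cell[c, ] <- colMeans(kb %*% t(ratio))
    }
    # secular non-beverage trend (common to all arms)
    nonbev <- config$nonbev_trend * seq_len(horizon)
    di <- sweep(di, 2, nonbev, "+")
    dgl <- sweep(dgl, 2, nonbev * config$nonbev_gl_per_kcal, "+")

    traj <- simulate_weight(pop, di, params = bundle$hall, horizon = horizon)
    bmi <- traj$weight[, -1, drop = FALSE] / pop$height^2

    for (c in seq_len(n_cells)) {
      rows <- which(cell_of == c)
      inc <- simulate_incidence(
        dgl[rows, , drop = FALSE], cells$diabetes_incidence[c],
        status0 = pop$diabetes[rows], params = bundle$hazard,
        horizon = horizon, u = u[rows, , drop = FALSE], t_offset = 0.5
      )
      out_rows[[length(out_rows) + 1L]] <- tibble(
        scenario = scen,
        age = cells$age[c], sex = cells$sex[c], income = cells$income[c],
        residence = cells$residence[c], weight = cells$weight[c],
        year = years,
        overweight = colMeans(bmi[rows, , drop = FALSE] >= 25),
        incidence = inc$incidence,
        incidence_observed = inc$observed,
        kcal = kcal_mean_cell[c, ]
      )
    }
  }
  out <- dplyr::bind_rows(out_rows)
  class(out) <- c("ssb_outcomes", class(out))
  attr(out, "config") <- config
  attr(out, "seed") <- seed
  out
}

#' Population-weighted overall outcomes
#'
#' Aggregates cohort-cell outcomes to the overall adult population (or to
#' one demographic margin) using the cell population weights.
#'
#' @param outcomes `ssb_outcomes` from [run_scenario()].
#' @param by Optional margin column (`"age"`, `"sex"`, `"income"`,
#'   `"residence"`) to retain.
#' @return Tibble with scenario, (margin,) year, `overweight`, `incidence`,
#'   `kcal`.
#' @export
aggregate_outcomes <- function(outcomes, by = NULL) {
  grp <- c("scenario", by, "year")
  outcomes |>
    dplyr::group_by(dplyr::across(dplyr::all_of(grp))) |>
    dplyr::summarise(
      overweight = sum(.data$weight * .data$overweight) / sum(.data$weight),
      incidence = sum(.data$weight * .data$incidence) / sum(.data$weight),
      kcal = sum(.data$weight * .data$kcal) / sum(.data$weight),
      .groups = "drop"
    )
}

#' Relative reductions of a taxed scenario against the baseline
#'
#' @param outcomes `ssb_outcomes` containing the two scenarios.
#' @param scenario Taxed scenario label (e.g. `"tax20"`).
#' @param by Optional margin column for per-margin contrasts.
#' @param year Year at which the contrast is evaluated (default: final).
#' @return Tibble with the relative reduction (percent) in overweight
#'   prevalence and diabetes incidence, plus the underlying levels.
#' @export
contrast_outcomes <- function(outcomes, scenario = "tax20", by = NULL,
                              year = NULL) {
  agg <- aggregate_outcomes(outcomes, by = by)
  year <- year %||% max(agg$year)
  a <- agg[agg$scenario == "baseline" & agg$year == year, ]
  b <- agg[agg$scenario == scenario & agg$year == year, ]
  if (nrow(b) == 0) abort(paste0("scenario not present: ", scenario))
  key <- if (is.null(by)) character(0) else by
  if (!length(key)) {
    m <- tibble(
      year = a$year,
      overweight_base = a$overweight, overweight_tax = b$overweight,
      incidence_base = a$incidence, incidence_tax = b$incidence
    )
  } else {
    m <- merge(a, b, by = c(key, "year"), suffixes = c("_base", "_tax"))
    m <- as_tibble(m[, c(key, "year", "overweight_base", "overweight_tax",
                         "incidence_base", "incidence_tax")])
  }
  m$overweight_reduction_pct <-
    100 * (m$overweight_base - m$overweight_tax) / m$overweight_base
  m$incidence_reduction_pct <-
    100 * (m$incidence_base - m$incidence_tax) / m$incidence_base
  m
}

#' Propagate parameter uncertainty by outer Monte-Carlo sampling
#'
#' Repeats the paired simulation with parameter bundles drawn from the input
#' uncertainty distributions ([draw_parameter_bundle()]), holding the inner
#' random numbers fixed across draws so the interval reflects parameter
#' uncertainty. Returns percentile intervals for the overall contrasts.
#'
#' @param config [scenario_config()].
#' @param n_outer Number of outer draws (>= 2).
#' @param n_per_cohort Individuals per cohort cell.
#' @param seed Integer master seed.
#' @param tax_rates Tax rates simulated against the shared baseline.
#' @param identical_draws If `TRUE` every draw uses the central bundle
#'   (degenerate sampling; zero-width intervals) — used for validation.
#' @return List of class `ssb_uncertainty`: `draws` (tibble of per-draw
#'   contrasts), `summary` (mean and 2.5/97.5 percentiles per scenario).
#' @export
uncertainty_run <- function(config = scenario_config(), n_outer = 200,
                            n_per_cohort = 2000, seed = 1,
                            tax_rates = config$tax_rate,
                            identical_draws = FALSE) {
  if (n_outer < 2) abort("n_outer must be >= 2")
  draws <- list()
  for (r in seq_len(n_outer)) {
    bundle <- if (identical_draws) parameter_bundle() else
      draw_parameter_bundle(child_seed(seed, 2000 + r))
    out <- run_scenario(config, n_per_cohort = n_per_cohort, seed = seed,
                        tax_rates = tax_rates, bundle = bundle)
    for (tau in tax_rates) {
      scen <- sprintf("tax%02d", round(100 * tau))
      ct <- contrast_outcomes(out, scenario = scen)
      ct$draw <- r
      ct$scenario <- scen
      draws[[length(draws) + 1L]] <- ct
    }
  }
  draws <- dplyr::bind_rows(draws)
  summary <- draws |>
    dplyr::group_by(.data$scenario) |>
    dplyr::summarise(dplyr::across(
      c("overweight_reduction_pct", "incidence_reduction_pct"),
      list(mean = mean,
           lo = ~ quantile(.x, 0.025, names = FALSE),
           hi = ~ quantile(.x, 0.975, names = FALSE))
    ), .groups = "drop")
  structure(list(draws = draws, summary = summary, n_outer = n_outer),
            class = "ssb_uncertainty")
}

#' @export
print.ssb_uncertainty <- function(x, ...) {
  cat("Monte-Carlo uncertainty summary (", x$n_outer, "outer draws )\n")
  print(x$summary)
  invisible(x)
}

#' Absolute cases averted
#'
#' Converts relative declines into absolute case counts: prevalent
#' overweight cases averted are the final-year prevalence difference times
#' the population; diabetes cases averted accumulate the yearly incidence
#' differences over the horizon.
#'
#' @param outcomes `ssb_outcomes` containing baseline and the taxed
#'   scenario.
#' @param scenario Taxed scenario label.
#' @param population Adult population represented (default: the packaged
#'   total for ages 25-65).
#' @param by Optional margin for per-margin counts (population split by the
#'   margin shares).
#' @return Tibble with `overweight_averted` and `diabetes_averted`.
#' @export
cases_averted <- function(outcomes, scenario = "tax20", population = NULL,
                          by = NULL) {
  struct <- cohort_structure_table()
  population <- population %||%
    struct$share[struct$margin == "population"]
  if (length(population) == 0 || any(population < 0)) {
    abort("missing population count")
  }
  agg <- aggregate_outcomes(outcomes, by = by)
  grp <- if (is.null(by)) character(0) else by
  base <- agg[agg$scenario == "baseline", ]
  tax <- agg[agg$scenario == scenario, ]
  if (nrow(tax) == 0) abort(paste0("scenario not present: ", scenario))
  key <- c(grp, "year")
  m <- merge(base, tax, by = key, suffixes = c("_base", "_tax"))
  if (length(grp)) {
    sh <- setNames(struct$share[struct$margin == by],
                   struct$level[struct$margin == by])
    m$pop <- population * sh[m[[by]]]
  } else {
    m$pop <- population
  }
  res <- m |>
    dplyr::group_by(dplyr::across(dplyr::all_of(grp))) |>
    dplyr::summarise(
      overweight_averted = (
        .data$overweight_base[which.max(.data$year)] -
          .data$overweight_tax[which.max(.data$year)]) *
        .data$pop[which.max(.data$year)],
      diabetes_averted = sum((.data$incidence_base - .data$incidence_tax) /
                               1e5 * .data$pop),
      .groups = "drop"
    )
  as_tibble(res)
}
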