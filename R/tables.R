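#' Packaged parameter tables
#'
#' Loaders for the parameter tables shipped with the package: price
#' elasticities of beverage demand with respect to the SSB price (by
#' demographic margin, with 95% CIs), baseline beverage kilocalorie intake /
#' overweight prevalence / diabetes incidence by cohort margin, glycemic load
#' per kilocalorie, beverage energy density, energy-metabolism parameters of
#' the body-weight model, diabetes hazard parameters, and the demographic
#' structure used to weight simulation cohorts.
#'
#' @param file Base name of a table under `inst/extdata`.
#' @return A tibble (`ssb_table()`), or a named object for the specialised
#'   accessors below.
#' @name ssb-tables
NULL

ssb_table <- function(file) {
  path <- system.file("extdata", file, package = "ssbtax")
  if (path == "") {
    # during development (package loaded with load_all) fall back to source tree
    path <- file.path("inst", "extdata", file)
  }
  if (!file.exists(path)) {
    abort(paste0("packaged table not found: ", file))
  }
  as_tibble(read.csv(path, comment.char = "#", stringsAsFactors = FALSE))
}

#' @rdname ssb-tables
#' @param cohort Demographic margin level: one of `"low"`, `"mid"`, `"high"`,
#'   `"urban"`, `"rural"` or `"overall"`.
#' @export
elasticity_table <- function(cohort = NULL) {
  tab <- ssb_table("elasticities.csv")
  if (!is.null(cohort)) {
    if (!cohort %in% tab$cohort) abort(paste0("unknown cohort: ", cohort))
    tab <- tab[tab$cohort == cohort, ]
  }
  tab
}

#' Point elasticities of each beverage to the SSB price for one cohort
#'
#' @inheritParams elasticity_table
#' @return Named numeric vector over the five beverages.
#' @export
ssb_price_elasticities <- function(cohort = "overall") {
  tab <- elasticity_table(cohort)
  setNames(tab$estimate, tab$beverage)[BEVERAGES]
}

#' @rdname ssb-tables
#' @export
beverage_baseline_table <- function() {
  ssb_table("beverage_baseline.csv")
}

#' Baseline row for one cohort margin level
#'
#' @param level A margin level (e.g. `"overall"`, `"urban"`, `"25-44"`).
#' @return One-row tibble with per-beverage kcal/day, overweight prevalence
#'   (percent of adults with BMI >= 25) and diabetes incidence per 100,000.
#' @export
baseline_row <- function(level = "overall") {
  tab <- beverage_baseline_table()
  row <- tab[tab$level == level, ]
  if (nrow(row) != 1L) abort(paste0("no baseline calibration row for level: ", level))
  row
}

#' @rdname ssb-tables
#' @export
nutrient_table <- function() {
  gl <- ssb_table("glycemic_load.csv")
  kc <- ssb_table("kcal_per_gram.csv")
  out <- dplyr::left_join(gl, kc, by = "beverage",
                          suffix = c("_gl", "_kcal"))
  names(out)[names(out) == "lo_gl"] <- "gl_lo"
  names(out)[names(out) == "hi_gl"] <- "gl_hi"
  names(out)[names(out) == "lo_kcal"] <- "kcal_lo"
  names(out)[names(out) == "hi_kcal"] <- "kcal_hi"
  out
}

#' @rdname ssb-tables
#' @export
hall_parameter_table <- function() {
  ssb_table("hall_parameters.csv")
}

#' @rdname ssb-tables
#' @export
hazard_parameter_table <- function() {
  ssb_table("hazard_parameters.csv")
}

#' @rdname ssb-tables
#' @export
cohort_structure_table <- function() {
  ssb_table("cohort_structure.csv")
}
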