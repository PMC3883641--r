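#' Convert beverage kilocalories to glycemic load
#'
#' Multiplies kilocalories per day by the beverage's effective glycemic load
#' per kilocalorie (grams of glycemic load per kcal, accounting for typical
#' serving sizes and consumer-added sugar in coffee and tea). Linear in kcal.
#'
#' @param kcal Kilocalories per day (>= 0), vectorised.
#' @param beverage Beverage label (recycled against `kcal`).
#' @param table Nutrient conversion table ([nutrient_table()] layout).
#' @param factor Which column to use: the point estimate (default) or a
#'   sampled per-beverage factor (named vector) in the uncertainty loop.
#' @return Glycemic load in grams per day.
#' @export
kcal_to_glycemic_load <- function(kcal, beverage, table = nutrient_table(),
                                  factor = NULL) {
  if (any(kcal < 0)) abort("kcal must be >= 0")
  if (is.null(factor)) factor <- setNames(table$gl_per_kcal, table$beverage)
  if (!all(beverage %in% names(factor))) {
    abort(paste0("unknown beverage label: ",
                 paste(setdiff(beverage, names(factor)), collapse = ", ")))
  }
  kcal * unname(factor[beverage])
}

#' Convert beverage grams to kilocalories
#'
#' @param grams Grams per day (>= 0), vectorised.
#' @inheritParams kcal_to_glycemic_load
#' @return Kilocalories per day.
#' @export
grams_to_kcal <- function(grams, beverage, table = nutrient_table()) {
  if (any(grams < 0)) abort("grams must be >= 0")
  factor <- setNames(table$kcal_per_g, table$beverage)
  if (!all(beverage %in% names(factor))) {
    abort(paste0("unknown beverage label: ",
                 paste(setdiff(beverage, names(factor)), collapse = ", ")))
  }
  grams * unname(factor[beverage])
}

#' Total beverage kilocalories for a cohort calibration row
#'
#' Arithmetic sum of the five per-beverage kilocalorie entries of a baseline
#' calibration row.
#'
#' @param row One-row tibble in the [beverage_baseline_table()] layout (or a
#'   named vector with `<beverage>_kcal` entries).
#' @return Total kcal/day from beverages.
#' @export
total_beverage_kcal <- function(row) {
  cols <- paste0(BEVERAGES, "_kcal")
  if (is.data.frame(row)) {
    if (!all(cols %in% names(row))) {
      abort(paste0("missing beverage entry: ",
                   paste(setdiff(cols, names(row)), collapse = ", ")))
    }
    vals <- as.numeric(row[1, cols])
  } else {
    if (!all(cols %in% names(row))) abort("missing beverage entry")
    vals <- as.numeric(row[cols])
  }
  sum(vals)
}

# Per-beverage kcal vector from a calibration row.
baseline_kcal_vector <- function(row) {
  setNames(as.numeric(row[1, paste0(BEVERAGES, "_kcal")]), BEVERAGES)
}
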