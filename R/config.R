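#' Load a scenario configuration from a YAML file
#'
#' Reads a YAML configuration, validates every key, fills defaults for
#' anything omitted (an empty file yields the full default: 20% tax, linear
#' trend, 2014-2023) and returns a validated [scenario_config()] plus any
#' simulation settings.
#'
#' Recognised keys: `tax_rate`, `trend`, `years` (either a vector or
#' `{from, to}`), `growth`, `growth_type`, `bass_anchors` (year: value map),
#' `bass_origin`, `nonbev_trend`, `nonbev_gl_per_kcal`, `n_per_cohort`,
#' `n_outer`, `seed`.
#'
#' @param path Path to the YAML file; `NULL` returns the defaults.
#' @return List with `config` (`ssb_scenario_config`) and `run` (list of
#'   simulation-size settings).
#' @export
load_config <- function(path = NULL) {
  raw <- list()
  if (!is.null(path)) {
    if (!file.exists(path)) abort(paste0("config file not found: ", path))
    raw <- yaml::read_yaml(path)
    if (is.null(raw)) raw <- list()
  }
  known <- c("tax_rate", "trend", "years", "growth", "growth_type",
             "bass_anchors", "bass_origin", "nonbev_trend",
             "nonbev_gl_per_kcal", "n_per_cohort", "n_outer", "seed")
  bad <- setdiff(names(raw), known)
  if (length(bad)) {
    abort(paste0("unknown configuration key: ", paste(bad, collapse = ", ")))
  }
  years <- raw$years
  if (!is.null(years) && is.list(years)) {
    years <- seq(years$from, years$to)
  }
  args <- list(
    tax_rate = raw$tax_rate %||% 0.20,
    trend = raw$trend %||% "linear",
    years = years %||% 2014:2023,
    growth = raw$growth %||% 0.13,
    growth_type = raw$growth_type %||% "increment",
    bass_origin = raw$bass_origin %||% 1998,
    nonbev_trend = raw$nonbev_trend %||% 8,
    nonbev_gl_per_kcal = raw$nonbev_gl_per_kcal %||% 0.12
  )
  if (!is.null(raw$bass_anchors)) {
    args$bass_anchors <- unlist(raw$bass_anchors)
  }
  config <- do.call(scenario_config, args)
  run <- list(
    n_per_cohort = raw$n_per_cohort %||% 2000,
    n_outer = raw$n_outer %||% 200,
    seed = raw$seed %||% 1
  )
  if (run$n_per_cohort < 1 || run$n_outer < 2) {
    abort("n_per_cohort must be >= 1 and n_outer >= 2")
  }
  list(config = config, run = run)
}

#' Write a configuration back to YAML
#'
#' Round-trips with [load_config()]: dumping and reloading yields an
#' identical configuration object.
#'
#' @param loaded A list as returned by [load_config()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_config <- function(loaded, path) {
  cfg <- loaded$config
  out <- list(
    tax_rate = cfg$tax_rate, trend = cfg$trend,
    years = list(from = min(cfg$years), to = max(cfg$years)),
    growth = cfg$growth, growth_type = cfg$growth_type,
    bass_anchors = as.list(cfg$bass_anchors),
    bass_origin = cfg$bass_origin, nonbev_trend = cfg$nonbev_trend,
    nonbev_gl_per_kcal = cfg$nonbev_gl_per_kcal,
    n_per_cohort = loaded$run$n_per_cohort, n_outer = loaded$run$n_outer,
    seed = loaded$run$seed
  )
  yaml::write_yaml(out, path)
  invisible(path)
}

#' Reproducibility manifest for a run
#'
#' Captures everything needed to reproduce an output bit for bit: the seed,
#' the scenario configuration, simulation sizes, package version and hashes
#' of the packaged parameter tables.
#'
#' @param loaded As returned by [load_config()].
#' @return List suitable for `jsonlite::write_json()`.
#' @export
run_manifest <- function(loaded) {
  files <- list.files(system.file("extdata", package = "ssbtax"),
                      full.names = TRUE)
  hashes <- vapply(files, function(f) {
    # small stable content hash without extra dependencies
    x <- readBin(f, "raw", file.info(f)$size)
    sprintf("%08x", sum(as.integer(x) * (seq_along(x) %% 251)) %% 4294967291)
  }, "")
  names(hashes) <- basename(files)
  list(
    package = "ssbtax",
    version = as.character(utils::packageVersion("ssbtax")),
    timestamp = format(Sys.time(), tz = "UTC", usetz = TRUE),
    seed = loaded$run$seed,
    n_per_cohort = loaded$run$n_per_cohort,
    n_outer = loaded$run$n_outer,
    config = list(
      tax_rate = loaded$config$tax_rate, trend = loaded$config$trend,
      years = range(loaded$config$years), growth = loaded$config$growth,
      growth_type = loaded$config$growth_type,
      nonbev_trend = loaded$config$nonbev_trend,
      nonbev_gl_per_kcal = loaded$config$nonbev_gl_per_kcal
    ),
    table_hashes = as.list(hashes)
  )
}
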