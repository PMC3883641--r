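#' Energy-metabolism parameters of the body-weight model
#'
#' Loads the two-compartment energy-balance parameters (energy densities of
#' fat and lean tissue, resting-metabolic-rate regression coefficients,
#' thermic effect of food, adaptive thermogenesis, Forbes lean-fat
#' partitioning constant, and the glycogen/extracellular-water bookkeeping
#' constants), with optional overrides.
#'
#' @param ... Named overrides of individual parameters.
#' @return Named list of class `ssb_hall_params`.
#' @export
hall_parameters <- function(...) {
  tab <- hall_parameter_table()
  par <- setNames(as.list(tab$value), tab$parameter)
  dots <- list(...)
  if (length(dots)) {
    bad <- setdiff(names(dots), names(par))
    if (length(bad)) abort(paste0("unknown Hall parameter: ",
                                  paste(bad, collapse = ", ")))
    par[names(dots)] <- dots
  }
  if (par$rho_fat <= par$rho_lean || par$rho_lean <= 0) {
    abort("energy densities must satisfy rho_fat > rho_lean > 0")
  }
  structure(par, class = "ssb_hall_params")
}

# Body-fat fraction at baseline (Deurenberg anthropometric regression).
body_fat_fraction <- function(bmi, age, sex) {
  male <- as.numeric(sex == "M")
  bf <- (1.20 * bmi + 0.23 * age - 10.8 * male - 5.4) / 100
  pmin(0.65, pmax(0.08, bf))
}

# Resting metabolic rate, kcal/day (Mifflin-St Jeor).
rmr_kcal <- function(weight, height, age, sex) {
  10 * weight + 625 * height - 5 * age + ifelse(sex == "M", 5, -161)
}

#' Initialise the energy-balance state of simulated individuals
#'
#' Each individual starts in energy balance: baseline intake equals
#' expenditure at the initial body composition. Fat mass comes from an
#' anthropometric regression on BMI, age and sex; the RMR intercept is
#' calibrated per individual so that the expenditure model reproduces that
#' equilibrium, giving every simulated adult their own initialisation rather
#' than a shared average body.
#'
#' @param individuals Tibble from [generate_individuals()] (needs `weight`,
#'   `height`, `bmi`, `sex`, `age_band`, `pal`).
#' @param params [hall_parameters()].
#' @return List of numeric vectors: `fat`, `lean`, `intake0` (equilibrium
#'   kcal/day), `activity` (kcal/kg/day), `k_rmr` (per-individual RMR
#'   intercept).
#' @export
hall_init <- function(individuals, params = hall_parameters()) {
  age_mid <- ifelse(individuals$age_band == "25-44", 35, 55)
  fat <- body_fat_fraction(individuals$bmi, age_mid, individuals$sex) *
    individuals$weight
  lean <- individuals$weight - fat
  rmr <- rmr_kcal(individuals$weight, individuals$height, age_mid,
                  individuals$sex)
  pal <- individuals$pal
  intake0 <- rmr * pal
  # weight-proportional physical activity; the individual's activity level
  # scales the population coefficient
  activity <- params$delta_activity * pal / params$pal_default
  # weight-independent remainder (baseline thermic effect of food, non-scaled
  # activity, individual RMR deviation) calibrated so intake0 is equilibrium
  k_rmr <- intake0 - params$gamma_fat * fat - params$gamma_lean * lean -
    activity * individuals$weight
  list(fat = fat, lean = lean, intake0 = intake0, activity = activity,
       k_rmr = k_rmr)
}

#' Equilibrium energy intake at current body composition
#'
#' The intake at which total energy expenditure equals intake, i.e. the
#' weight derivative is zero.
#'
#' @inheritParams hall_init
#' @return kcal/day per individual.
#' @export
equilibrium_intake <- function(individuals, params = hall_parameters()) {
  hall_init(individuals, params)$intake0
}

#' Simulate body-weight trajectories under intake changes
#'
#' Integrates the two-compartment (fat/lean) energy-balance system at daily
#' steps: the energy imbalance between intake and expenditure (RMR on fat
#' and lean mass, physical activity proportional to body weight, thermic
#' effect of the intake change, and optionally adaptive thermogenesis with a
#' first-order lag) is partitioned between lean and fat tissue by the Forbes
#' rule \eqn{p = C/(C + F)}, with a fast glycogen/extracellular-water pool
#' tracking relative intake. Deterministic; yearly snapshots are returned.
#'
#' @param individuals Tibble from [generate_individuals()].
#' @param delta_intake Intake change from baseline, kcal/day: a single
#'   number, a per-year vector, or an `n x years` matrix (constant within
#'   each simulated year).
#' @param params [hall_parameters()].
#' @param horizon Number of years to simulate.
#' @param adaptive Include adaptive thermogenesis (on by default; set
#'   `FALSE` for the model variant without it).
#' @param dt Integration step in days.
#' @return Object of class `ssb_weight_trajectory`: list of matrices
#'   (`weight`, `fat`, `lean`, each `n x (horizon + 1)`, column 1 =
#'   baseline), plus `energy_residual`, the maximum per-individual gap
#'   between cumulative energy imbalance and stored body energy, relative to
#'   total flux.
#' @export
simulate_weight <- function(individuals, delta_intake,
                            params = hall_parameters(), horizon = 10,
                            adaptive = TRUE, dt = 1) {
  stopifnot(horizon >= 1)
  n <- nrow(individuals)
  di <- delta_intake_matrix(delta_intake, n, horizon)
  if (any(!is.finite(di))) abort("delta_intake must be finite")

  st <- hall_init(individuals, params)
  fat <- st$fat; lean <- st$lean
  g0 <- params$glycogen_0
  gly <- rep(g0, n)
  at <- rep(0, n)
  steps_per_year <- round(365 / dt)

  W <- Fm <- Lm <- matrix(NA_real_, n, horizon + 1)
  W[, 1] <- individuals$weight; Fm[, 1] <- fat; Lm[, 1] <- lean

  cum_balance <- rep(0, n)
  cum_flux <- rep(1e-12, n)
  hw <- params$hydration_glycogen
  # Forbes mass rule dL/dF = C/F expressed as an energy partition fraction
  cpar <- params$forbes_c * params$rho_lean / params$rho_fat

  for (yr in seq_len(horizon)) {
    d <- di[, yr]
    rel_intake <- pmax(0, 1 + d / st$intake0)
    for (s in seq_len(steps_per_year)) {
      bw <- fat + lean + (1 + hw) * (gly - g0)
      expend <- st$k_rmr + params$gamma_fat * fat + params$gamma_lean * lean +
        st$activity * bw + params$beta_tef * d + at
      bal <- st$intake0 + d - expend
      if (adaptive) {
        at <- at + dt * (params$beta_at * d - at) / params$tau_at
      }
      dgly <- params$k_glycogen * (rel_intake - (gly / g0)^2)
      tissue <- bal - params$rho_glycogen * dgly
      p <- cpar / (cpar + fat)
      lean <- lean + dt * p * tissue / params$rho_lean
      fat <- fat + dt * (1 - p) * tissue / params$rho_fat
      gly <- pmax(0, gly + dt * dgly)
      if (any(fat <= 0) || any(lean <= 0)) {
        abort("integration failure: body compartment depleted (intake deficit too large)")
      }
      cum_balance <- cum_balance + dt * bal
      cum_flux <- cum_flux + dt * abs(bal)
    }
    W[, yr + 1] <- fat + lean + (1 + hw) * (gly - g0)
    Fm[, yr + 1] <- fat
    Lm[, yr + 1] <- lean
  }
  stored <- params$rho_fat * (fat - st$fat) + params$rho_lean * (lean - st$lean) +
    params$rho_glycogen * (gly - g0)
  structure(list(
    weight = W, fat = Fm, lean = Lm,
    energy_residual = max(abs(cum_balance - stored) / cum_flux)
  ), class = "ssb_weight_trajectory")
}

delta_intake_matrix <- function(delta_intake, n, horizon) {
  if (is.matrix(delta_intake)) {
    stopifnot(nrow(delta_intake) == n, ncol(delta_intake) == horizon)
    return(delta_intake)
  }
  if (length(delta_intake) == 1L) {
    return(matrix(delta_intake, n, horizon))
  }
  stopifnot(length(delta_intake) == horizon)
  matrix(delta_intake, n, horizon, byrow = TRUE)
}

#' Algebraic steady-state weight under a sustained intake change
#'
#' Independent of the trajectory integrator: solves the energy-balance
#' equation at steady state by one-dimensional root finding on fat mass,
#' with lean mass tied to fat along the Forbes path
#' \eqn{L(F) = L_0 + C \log(F/F_0)} and the glycogen pool at
#' its equilibrium for the new intake. Used as the oracle the integrator is
#' checked against.
#'
#' @param individuals One-or-more-row tibble of individuals.
#' @param delta_intake Sustained intake change, kcal/day (scalar or length
#'   `n`).
#' @param params [hall_parameters()].
#' @param adaptive Include the adaptive-thermogenesis offset at steady state.
#' @return Steady-state body weight (kg) per individual.
#' @export
steady_state_weight <- function(individuals, delta_intake,
                                params = hall_parameters(), adaptive = TRUE) {
  st <- hall_init(individuals, params)
  n <- nrow(individuals)
  d <- rep(delta_intake, length.out = n)
  hw <- params$hydration_glycogen
  g0 <- params$glycogen_0
  vapply(seq_len(n), function(i) {
    gs <- g0 * sqrt(pmax(0, 1 + d[i] / st$intake0[i]))
    at_ss <- if (adaptive) params$beta_at * d[i] else 0
    lean_of <- function(f) {
      st$lean[i] + params$forbes_c * log(f / st$fat[i])
    }
    bal <- function(f) {
      l <- lean_of(f)
      bw <- f + l + (1 + hw) * (gs - g0)
      st$intake0[i] + d[i] -
        (st$k_rmr[i] + params$gamma_fat * f + params$gamma_lean * l +
           st$activity[i] * bw + params$beta_tef * d[i] + at_ss)
    }
    f_star <- uniroot(bal, c(st$fat[i] * 1e-3, st$fat[i] * 50),
                      tol = 1e-10)$root
    f_star + lean_of(f_star) + (1 + hw) * (gs - g0)
  }, 0)
}
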