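---
title: "Methods: an SSB-tax health microsimulation for India"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: an SSB-tax health microsimulation for India}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ssbtax)
```

This vignette is the package's account of its science: the models it
chains together, the assumptions each one makes, the parameters that
matter, and the choices taken where the design was genuinely open.

## 1. The demand system

Beverage demand is a Quadratic Almost Ideal Demand System (QUAIDS) over
five beverage classes — milk, sugar-sweetened beverages (SSBs), fresh
fruit juice, coffee, tea — plus a composite *outside good* holding all
non-beverage expenditure at numeraire price. The outside good is not a
cosmetic addition: the packaged elasticity column (own-price −0.94 for
SSBs with *positive* cross-elasticities for milk, juice and tea) is
incompatible with Cournot aggregation in any closed five-beverage system,
because the weighted column sum must equal the negative SSB budget share.
Households must be able to move expenditure out of (or into) the beverage
market; the sixth good supplies exactly that margin, and with it all
demand-theory identities hold to machine precision (tested).

Zero purchases are endemic in expenditure surveys, so estimation uses the
standard two-step censored-system correction: a probit of the purchase
indicator per beverage yields fitted probabilities Φ̂ and densities φ̂,
and the observed-share equation for beverage *i* becomes
*wᵢ = Φ̂ᵢ·fᵢ(p, m; θ) + ξᵢ·φ̂ᵢ + ε*. The share system is then fitted by
**iterated feasible least squares**: given current coefficients, the
translog price index a(p) and the Cobb–Douglas aggregator b(p) are fixed,
the stacked five-equation system is solved as one restricted linear
problem (symmetry imposed by sharing γ coefficients across equations),
and the indices are updated. Convergence tolerance is 10⁻⁸ on the
parameter step with a 100-iteration cap; on noise-free data the iteration
reaches the generating parameters to machine precision in about four
steps. The outside good's equation is the one omitted; its coefficients
are recovered from adding-up, homogeneity and symmetry, so the fitted
shares sum to one at every record by construction.

Choices worth recording:

* **Normalisation.** Prices and expenditure are expressed relative to
  sample medians and the translog intercept α₀ is fixed at 0 there (it is
  not separately identified). Elasticities are evaluated at that base
  point — median prices, median expenditure — where the fitted α̂ equal
  the latent (consumption-corrected) mean budget shares.
* **No expenditure instrument.** Total expenditure is treated as
  exogenous; with no credible instrument available this is a documented
  limitation, not a configuration option.
* **Confidence intervals** come from a nonparametric bootstrap over
  households (default 200 replicates, seeded, warm-started at the point
  estimate). A delta-method alternative was not implemented; the bootstrap
  also exercises the first stage.

## 2. Synthetic data with known ground truth

The two surveys this kind of analysis rests on — a household consumer
expenditure module and an individual anthropometric/health survey — are
not publicly deposited, so the package generates both synthetically, with
the data-generating parameters exposed as a `GroundTruth` object.

**Households** (`generate_households()`): log-prices are drawn around
cohort medians, truncated to a ±17.5% band (reproducing a ~35% SSB price
variation range); total expenditure is lognormal; budget shares come from
the ground-truth QUAIDS system plus Gaussian share noise (SD 0.004); and
an independent latent-propensity censoring step zeroes a configurable
fraction of purchases per beverage (defaults: milk 10%, SSBs 40%, juice
60%, coffee 50%, tea 10%), with the probit intercept solved so the
*marginal* zero fraction is exact. The ground-truth QUAIDS coefficients
are solved so that, at the base point, the implied elasticity column with
respect to the SSB price equals the packaged table exactly. Quantities
the table does not pin down use fixed, documented defaults: beverage
budget shares (milk 0.107, SSB 0.040, juice 0.020, coffee 0.018, tea
0.040), expenditure elasticities (1.05, 1.40, 1.50, 1.20, 0.90), own-price
elasticities of the non-SSB beverages (−0.75, −1.10, −0.90, −0.65) and
small beverage–beverage cross terms. Share-equation error variances and
censoring rates are not published quantities; they are configuration, not
inference.

**Individuals** (`generate_individuals()`): BMI is lognormal — the
right-skewed shape such surveys show — with the log-scale SD solved once
from the overall anchor (mean 24 kg/m², overweight prevalence 38%) and
the location solved per cohort so that P(BMI ≥ 25) equals the cohort's
calibrated prevalence exactly. Per-beverage intakes are gamma with the
calibrated means and CV 0.5, coupled to BMI through a Gaussian copula
with rank correlation 0.2 (a joint distribution is required; no
correlation value is published, so it is configurable). Baseline diabetes
status is Bernoulli with prevalence approximated as incidence × 25 years
of mean disease duration (~7.7% overall). Heights are sex-specific
normals (1.65/1.53 m).

Only margins of the 2×2×3×2 cohort design are published, so cell values
combine margin effects independently — multiplicatively for kilocalories
and incidence, additively on the logit scale for prevalence — then
rescale so the population-weighted cells reproduce the overall row
exactly. This independence is a stated approximation; real cells surely
interact. Cell population weights are products of census-style margin
shares (62% aged 25–44, 51.5% male, equal income tertiles, 31% urban).

What passing tests therefore show: the estimators recover parameters from
data *of this structure*. What they cannot show: robustness to survey
features the generator omits — sampling weights, district clustering,
measurement error in prices, correlated censoring across beverages, or
joint cell-level interactions.

## 3. Scenarios and the tax shock

The tax conversion is deliberately first-order: Δkcalᵦ =
e<sub>b,SSB</sub> × 100τ × kcalᵦ/100, floored so consumption cannot go
negative, applied to every year of the baseline path from the tax start
(2014). Elasticities are held constant over the horizon, and pass-through
to consumer prices is 100%. Because the shock is linear in τ, effect
ratios across tax rates of 10/20/30% are close to 1:2:3 by construction —
the model produces no strong rate asymmetry in the diabetes response (see
§6).

The **linear baseline** grows SSB kilocalories by 13% of the 2014 level
per year (constant increments; a compound-growth switch exists because
"13% per annum" admits both readings — compounding reaches ~138 kcal by
2023 versus ~100 kcal with increments). Non-SSB beverages are flat, their
historical trends being statistically indistinguishable from zero. A
secular non-beverage calorie drift (default +8 kcal/day per year, a
food-balance-sheet-scale rise for India in the 2000s, with glycemic load
0.12 g/kcal for a mixed high-carbohydrate diet) is applied equally to all
arms; it moves baseline trajectories, not tax contrasts.

The **Bass baseline** follows a diffusion curve
S(t) = m(1−e^{−(p+q)t})/(1+(q/p)e^{−(p+q)t}) with the clock starting in
1998. The three calibration anchors (11 l/person/yr in 2012; 12.8 in
2014; 36.3 in 2023) are not jointly representable by any Bass curve —
growth accelerates faster after 2014 than a curve through the 2012 level
allows — so calibration honours the two projection endpoints exactly
(root-solving the innovation rate inside a one-dimensional optimisation
of the imitation rate) and fits 2012 in least squares. The solution sits
in the small-*p*, imitation-dominated limit (q ≈ 0.10), an essentially
exponential adoption phase.

## 4. Body weight

Weight dynamics use the validated two-compartment energy-balance
formulation: fat and lean compartments with energy densities 9441 and
1807 kcal/kg, resting expenditure 3.2·F + 22·L plus a per-individual
intercept, physical activity proportional to body weight
(7.1 kcal/kg/day at the default activity level, scaled by each
individual's PAL), thermic effect of food (10% of the intake change) and
adaptive thermogenesis (14% with a 14-day first-order lag; a flag
disables it for the model variant without). The energy imbalance is
partitioned by the Forbes rule — expressed as an energy fraction
p = C̃/(C̃+F) with C̃ = 10.4·ρ_L/ρ_F, which reproduces the Forbes mass
relation dL/dF = 10.4/F — plus a fast glycogen pool (0.5 kg, hydration
2.7 g water/g) tracking relative intake.

Every individual starts in energy balance at their own anthropometry
(intake = RMR × PAL, RMR from a standard anthropometric equation), so
cohorts carry their full heterogeneity rather than an average body.
Integration is explicit Euler at 1-day steps with yearly snapshots;
energy conservation holds to ~10⁻¹² of cumulative flux, and the
integrator is checked against an independent algebraic steady-state
oracle (root-finding on fat mass along the Forbes path). A sustained
−100 kcal/day costs a reference adult ≈ 4.2 kg at steady state, with
about two-thirds realised after one year — the time delay that motivates
a dynamic model. Compartment depletion (unphysically large deficits)
raises an error rather than returning nonsense.

## 5. Diabetes hazard

A change in daily glycemic load ΔGL (grams/day, measured against the
pre-period consumption level) multiplies the cohort baseline incidence by
exp[ln(RR)·(ΔGL/100)·(1−e^{−rt})], with RR = 1.45 per 100 g/day (95% CI
1.31–1.61) and r = 1/7.6 yr⁻¹ (CI 1/14.7–1/2.8). The phase-in is applied
to the current-year ΔGL with the clock starting at the tax (mid-year
offset 0.5); the alternative reading — exponential decay of excess risk
after exposure removal — is mathematically identical here. The glycemic-
load RR is used instead of an SSB-specific RR precisely so that
substituted beverages' metabolic effects count, and no separate
BMI-mediated diabetes pathway is added, since the RR already incorporates
obesity-mediated and obesity-independent routes. Diabetes is absorbing;
there is no background mortality or remission, a simplification a 10-year
horizon tolerates.

Within the microsimulation, transitions are Bernoulli draws against
common random numbers, while *reported* incidence is the expected rate
among the at-risk (the mean transition probability × 100,000). This
Rao–Blackwellised rate removes binomial noise from scenario contrasts —
which are differences of order a few per 100,000 — without altering the
state dynamics the draws produce.

## 6. The microsimulation and what it reproduces

`run_scenario()` samples all 24 cohorts once, builds baseline and taxed
consumption paths, scales each individual's intake change by their own
beverage profile, and runs the weight and hazard models; baseline and
taxed arms share individuals and random streams, so contrasts are paired.
`uncertainty_run()` wraps this in an outer Monte-Carlo loop: every
parameter reported with a CI or SE (elasticities, glycemic loads,
calibration moments, RR, effect rate, metabolic coefficients) is drawn
from a normal implied by it (SD = CI width/3.92), truncated where signs
are constrained, with the inner random numbers held fixed across draws.
Desk-scale defaults are 2,000 individuals per cohort and 200 outer draws
(the design this emulates used 10,000 × 10,000); the defaults are
config-overridable and the test suite runs smaller sizes still.

Two families of published magnitudes behave differently under this
pipeline, and the distinction is a property of the model, not a tuning
choice:

* **Overweight outcomes follow the energy arithmetic.** A 20% tax removes
  a net ~2.4 kcal/day in 2014, growing to ~12 kcal/day by 2023 as the
  baseline rises; through the weight model's lag this yields a ~2.7–3%
  relative reduction in overweight prevalence by 2023, near-proportional
  scaling with the tax rate, and cohort effects largest where median BMI
  sits furthest below the 25 kg/m² threshold (young, rural, low-income
  groups) — the distributional pattern such analyses report.
* **Diabetes outcomes are bounded by the glycemic-load arithmetic.** The
  same shock changes glycemic load by only ~−1 g/day in 2014 (~−2.6 by
  2023); with RR 1.45 per 100 g/day and the 1/7.6 yr⁻¹ phase-in, the
  incidence reduction the hazard can deliver is ~0.7% (and ~0.9% under
  the Bass baseline) — materially smaller than the 1.5–2.5% figures
  published for comparable taxes, which would require roughly −6 g/day.
  Published rate *asymmetries* across 10/20/30% taxes likewise cannot
  arise from a shock linear in τ. Reproducing those magnitudes would
  require mechanisms beyond the printed parameter set (for example a
  direct BMI–diabetes pathway), which this package deliberately does not
  invent.

## 7. Known limitations

Beyond the points above: elasticities from a single cross-section stand
in for future behaviour; children, diet beverages, tax evasion and
revenue use are out of scope; the cohort-cell calibration assumes
independent margin effects; prices are generated in constant currency
units (no deflator machinery); and absolute cases-averted counts inherit
whatever population projections the user supplies (the packaged default
is a single 550-million adult total with fixed margin shares, not a
demographic projection).
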