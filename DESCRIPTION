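Package: ssbtax
Title: Health Impact Microsimulation of Sugar-Sweetened Beverage Taxation in India
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to estimate the effect of an excise tax on sugar-sweetened
    beverages (SSBs) on overweight and type 2 diabetes in Indian adults.
    Includes a censored Quadratic Almost Ideal Demand System (QUAIDS)
    estimator with a two-step probit correction for zero purchases,
    synthetic household-expenditure and individual-health data generators
    with known ground truth, conversion of beverage intake to kilocalories
    and glycemic load, the Hall two-compartment energy-balance body-weight
    model, a lagged glycemic-load diabetes hazard, and a demographic-cohort
    microsimulation with common-random-number counterfactuals and outer
    Monte-Carlo propagation of parameter uncertainty.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    rlang,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr,
    ggplot2
Config/testthat/edition: 3
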