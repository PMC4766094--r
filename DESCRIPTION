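Package: cessmod
Title: Markov Cohort Cost-Effectiveness Modelling of Smoking-Cessation
    Treatment Coverage
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Six-state Markov cohort model comparing full statutory-health-
    insurance coverage of medically managed smoking cessation with a lump-sum
    drug subsidy, from the payer perspective. Builds age-, gender- and
    smoking-status-stratified mortality life tables for lung cancer, COPD and
    cardiovascular disease (including a calibrated synthetic generator),
    runs the cohort model with tunnel states for years since cessation,
    computes discounted costs, life-years and incremental cost-effectiveness
    ratios with chronic-disease cost offsets, and provides deterministic and
    Monte Carlo probabilistic sensitivity analysis, budget impact projection
    and external-validation summaries. Tidy interfaces throughout: tibbles
    in and out, broom-style tidiers, ggplot2 autoplot methods.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
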