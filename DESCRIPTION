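Package: lactaqg
Title: Quantitative Genetic Analysis of Dairy Test-Day Milk Records
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A pipeline for estimating genetic parameters of milk production
    traits (daily milk yield, fat percentage, protein percentage) from
    test-day records of dairy cattle. Provides pedigree handling (numerator
    relationship matrix, its sparse inverse, inbreeding coefficients), a
    tiered quality-control protocol with a per-stage audit report,
    descriptive trait summaries, least-squares means of non-genetic factors
    with Bonferroni-adjusted compact letter displays, and restricted
    maximum likelihood (REML) estimation of variance components under a
    repeatability animal model with additive genetic, maternal, and
    permanent-environment random effects, in single- and multi-trait form.
    A stochastic herd simulator (gene dropping on a generated pedigree)
    supplies data with known generative parameters for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    methods,
    stats,
    utils,
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    emmeans,
    jsonlite,
    readr,
    yaml
Suggests:
    testthat (>= 3.0.0),
    MASS,
    withr
Config/testthat/edition: 3
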