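Package: hatchsex
Title: Hormone-Based Sex Identification for Hatchling Tortoises
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Sex identification of externally monomorphic hatchling tortoises
    from plasma testosterone concentration quantified by competitive ELISA.
    Fits sex-specific lognormal (or gamma, Weibull) distributions to
    known-sex hormone panels with nonparametric bootstrap confidence
    intervals and Kolmogorov-Smirnov goodness of fit, derives probabilistic
    (density-ratio) and empirical-range decision thresholds, estimates
    misidentification rates by parametric Monte Carlo simulation
    propagating bootstrap parameter uncertainty, tests the effect of a
    follicle-stimulating hormone (FSH) challenge with a repeated-measures
    ANOVA and permutation tests on paired samples, and validates ELISA
    standard curves via four-parameter logistic fits and parallelism
    likelihood-ratio tests. Includes synthetic-data generators emulating
    every input the pipeline consumes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    car,
    dplyr,
    fitdistrplus,
    generics,
    ggplot2,
    jsonlite,
    minpack.lm,
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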