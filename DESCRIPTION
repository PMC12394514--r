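Package: coralscreen
Title: Thermal Tolerance Screening Analysis for Coral Restoration
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis toolkit for standardized acute heat-stress screening of
    reef corals (CBASS-style assays). Fits constrained three-parameter
    log-logistic dose-response curves to dark-acclimated photosynthetic
    efficiency (Fv/Fm) measurements to obtain ED50 thermal thresholds,
    computes site-standardized relative thresholds (ED50 - MMM), runs paired
    donor/nursery retention-recovery comparisons (normality-gated paired
    tests, unequal-n Tukey HSD, linear mixed models), quantifies colony-level
    ED50 reproducibility and top/bottom cohort-assignment consistency under
    subsampled screening effort, and tests growth-tolerance trade-offs from
    geometric-mean-radius growth records. Includes a seeded
    synthetic-campaign generator so the full pipeline is testable without
    field data.
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
    lme4,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0),
    knitr,
    rmarkdown
Config/testthat/edition: 3
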