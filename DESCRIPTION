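Package: setupbudget
Title: Setup-Uncertainty Decomposition and Budgets for Frameless 6D
    Image-Guided Stereotactic Radiotherapy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies individual and cumulative patient-positioning
    uncertainties of frameless 6D image-guided stereotactic radiotherapy
    (SRS/SRT) from per-fraction couch-shift records. Decomposes X-ray
    correction (XC) and verification (XV) shift streams into named
    systematic and random components (mask, setup, infrared frame,
    stereotactic localizer, X-ray registration), folds in Winston-Lutz
    isocentricity logs and couch-sag phantom tables, and combines the
    components into cumulative uncertainties under a linear-plus-quadrature
    model and under the GUM all-quadrature rule with coverage-factor
    expansion. Ships a synthetic-cohort generator with known ground truth
    so every estimator is testable by parameter recovery, plus tidy
    summaries, histograms and report rendering.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
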