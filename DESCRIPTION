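Package: psndelay
Title: Patient-Sharing Networks and Timely Cancer Treatment Initiation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end pipeline for studying whether physician
    patient-sharing networks (PSNs) are associated with 30-day delays in
    starting cancer treatment, using Medicare-like administrative claims.
    Includes a calibrated synthetic claims generator with known embedded
    effects (standing in for restricted SEER-Medicare linkages), an
    auditable eligibility cascade, diagnosing/treating provider dyad
    construction with shared-patient counts and tie strength, PSN
    classification with Kolmogorov-Smirnov cut-point validation,
    Charlson-Deyo comorbidity and dyad-homophily feature engineering,
    inverse-propensity weighting for complete-case selection, and a
    weighted multivariable logistic delay model with robust standard
    errors, descriptive tables with small-cell suppression, and
    broom-style tidiers.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    readr,
    stringr,
    ggplot2,
    jsonlite,
    lubridate,
    sandwich,
    survival,
    igraph,
    generics,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
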