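Package: inflammage
Title: Dietary Inflammation and Machine-Learning Brain Age Gap Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested, reusable pipeline linking the inflammatory potential of
    diet to accelerated brain aging. Implements Dietary Inflammatory Index (DII)
    scoring with energy-plausibility quality control and multi-assessment
    averaging, the INFLA-score decile composite of low-grade systemic
    inflammation, covariate derivation rules for epidemiological cohorts,
    brain-age estimation from imaging-derived phenotypes with leakage-free
    standardization and age-bias correction, covariate-adjusted association and
    stratified analyses of the brain age gap, and bootstrap linear mediation
    (ACME/ADE/proportion mediated). A synthetic cohort generator with known
    effect sizes and a known mediated fraction makes every stage testable
    without access-controlled cohort data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    glmnet,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    e1071,
    emmeans,
    jsonlite,
    knitr,
    rmarkdown,
    testthat (>= 3.0.0),
    xgboost
Config/testthat/edition: 3
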