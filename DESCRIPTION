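Package: anthroweight
Title: Validation of Anthropometric Weight-Prediction Equations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for validating anthropometric weight-prediction equations in
    adult cohorts. Provides a declarative registry of nine published linear
    equations (Chumlea, Rabito 1-3, Crandall, Lorenz, Kokong, Jung, Cattermole)
    that predict body weight from circumference, length and skinfold
    measurements; the accuracy framework standard in this literature (P10/P20
    within-tolerance percentages, mean percentage error, Bland-Altman bias and
    95% limits of agreement with confidence intervals); stratified validation
    by sex and WHO BMI nutrition category; a seeded synthetic cohort generator
    emulating a quota-sampled study design for planted-truth testing; and CSV
    ingest, descriptive statistics and report writers.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    jsonlite,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    readxl,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
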