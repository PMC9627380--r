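Package: eppm
Title: Early Prognosis Prediction Modelling for Traumatic Brain Injury
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements a point-based early prognosis prediction model (EPPM)
    for traumatic brain injury: grading rules that convert seven admission
    predictors (age, damaged lobe, Glasgow Coma Scale, APOE epsilon-4 carrier
    status, serum CRP and IL-8, Marshall CT class) into integer points,
    threshold classification of the total score, a predictor-screening
    pipeline (normality-gated univariate tests followed by multivariate
    logistic regression), ROC/Youden model evaluation, and a synthetic cohort
    generator that reproduces published outcome-conditional summary
    distributions so the whole pipeline is testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
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
    yaml
Suggests:
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
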