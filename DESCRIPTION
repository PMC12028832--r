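Package: ifcgrowth
Title: Fetal Growth Potential and Doppler Models for Intrapartum Fetal Compromise
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for assessing fetal growth potential from mid-pregnancy
    ultrasound and comparing it with Doppler haemodynamics for the prediction
    of intrapartum fetal compromise (IFC). Extrapolates the 20-week estimated
    fetal weight (EFW) to the third trimester through multiples of the median
    (MoM) to obtain the percentage of expected weight achieved (%ExFW3t),
    converts umbilical and middle cerebral artery pulsatility indices and the
    cerebroplacental ratio to MoM, and provides the model-comparison
    machinery: univariable and multivariable logistic regression with odds
    ratios and Wald intervals, AIC ranking with the two-unit rule, and ROC
    analysis with DeLong confidence intervals and detection rates at fixed
    false-positive rates. A seeded synthetic-cohort generator reproduces the
    statistical structure of a 777-pregnancy screening population so the whole
    pipeline is testable without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    stats,
    utils,
    jsonlite,
    readr,
    ggplot2,
    generics
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr
Config/testthat/edition: 3
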