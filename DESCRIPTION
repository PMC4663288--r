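Package: egsys
Title: Validation Toolkit for the EGSYS Cardiac Syncope Score
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Computes the univariate (EGSYS-U) and multivariate (EGSYS-M)
    variants of the Evaluation of Guidelines in Syncope Study score from
    per-patient clinical indicators and runs a complete diagnostic-accuracy
    validation against an adjudicated cardiac/noncardiac diagnosis:
    confusion matrices, sensitivity/specificity/predictive values with
    binomial confidence intervals, likelihood ratios (standard and
    posttest-odds forms), 2x2 odds ratios, ROC curves with trapezoidal AUC,
    the DeLong test for paired AUCs, Youden-index cut-off selection and a
    precision-based sample-size formula. A seeded synthetic-cohort
    generator with class-conditional Bernoulli risk-factor profiles makes
    the whole pipeline reproducible without patient-level data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
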