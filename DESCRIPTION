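Package: icdnext
Title: Next-Visit Prediction of Impulse Control Disorders in Parkinson's Disease
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates longitudinal Parkinson's disease cohorts with
    clinical scales, dopamine-agonist exposure and SNP dosages, builds
    next-visit prediction observations, and compares a trivial persistence
    baseline, reduced-history penalized logistic regressions and a
    GRU-static fusion network under nested subject-level cross-validation.
    Includes midrank ROC AUC, step-wise average precision, the DeLong test
    for correlated ROC AUCs with Bonferroni adjustment, and a synthetic
    cohort generator with known ground-truth effect directions.
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
    glmnet,
    ggplot2,
    generics,
    readr,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr
Config/testthat/edition: 3
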