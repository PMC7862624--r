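Package: fscm
Title: Flexible Scoring Card Method for Peptide Bioactivity Prediction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Estimates amino-acid and dipeptide propensity scorecards from
    labeled peptide sets, on whole sequences or N-/C-terminal regions, and
    classifies peptides by a composition-weighted sum of propensity scores
    against a learned threshold (the flexible scoring card method, FSCM).
    Initial scorecards are derived from class composition differences and
    min-max scaled to 0-1000; a genetic algorithm refines them under a
    fitness combining cross-validated AUC with correlation to the initial
    card. Includes terminal-region feature extraction, stratified
    evaluation (accuracy, sensitivity, specificity, MCC, ROC/AUC),
    correlation of amino-acid propensities with physicochemical property
    indices, and a synthetic peptide generator with planted dipeptide
    signal for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    utils,
    withr
Suggests:
    optparse,
    jsonlite,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
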