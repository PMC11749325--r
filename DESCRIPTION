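Package: neohai
Title: Antibiotic Decision-Making Analysis for Suspected Neonatal
    Healthcare-Associated Infection
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Implements an episode-level analysis pipeline for antibiotic
    decision-making in neonates investigated for suspected
    healthcare-associated infection (HAI): reference-standard HAI
    classification (proven / presumed / none, with coagulase-negative
    staphylococcus adjudication), the five-item NeoHoP infection prediction
    score, point-of-care C-reactive protein thresholding, a bedside
    antibiotic decision tool with theoretical length-of-therapy (LOT)
    assignment, diagnostic-accuracy evaluation (sensitivity, specificity,
    likelihood ratios, predictive values, accuracy, ROC AUC, binomial
    confidence intervals), an exhaustive-CHAID decision-tree builder over
    categorical predictors, nonparametric group comparisons
    (median/IQR, exact and approximate Mann-Whitney U), and a calibrated
    synthetic-cohort generator so the whole pipeline is testable without
    patient-level data.
License: MIT
Encoding: UTF-8
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    ggplot2,
    pROC
Config/testthat/edition: 3
RoxygenNote: 7.3.3
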