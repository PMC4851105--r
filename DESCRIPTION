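Package: swingemg
Title: Surface EMG Analysis of the Golf Swing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Analysis chain for multichannel surface electromyography (EMG)
    recorded during golf swings. Provides multiscale Gaussian onset detection
    and muscle activation-sequence profiling, automatic swing-segment
    extraction from the two dominant envelope peaks per channel, a registry of
    22 EMG feature sets, random-forest prediction of shot effectiveness with
    subject-grouped bootstrap sampling and out-of-bag scoring, decision-level
    fusion with angle-modulated differential evolution meta-feature selection,
    and calibrated detection (Cllr, DET/EER, ROC/AUC) and regression (RMSE,
    MAPE, correlation) evaluation. Includes a synthetic multichannel EMG
    generator with known ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ranger,
    signal,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
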