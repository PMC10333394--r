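Package: pacuseq
Title: Prolonged PACU Stay Prediction and Operating-Room Case Resequencing
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Predicts prolonged post-anesthesia care unit (PACU) length of
    stay from preoperative features under heavy class imbalance, then uses
    the predicted risk to resequence surgical cases within operating-room
    days and quantifies the change in after-hours (past 7pm) PACU occupancy.
    Includes a synthetic-cohort generator emulating an ambulatory surgery
    center population, SMOTE oversampling combined with random
    under-sampling, six classifier families with cross-validated and
    held-out evaluation (AUC, sensitivity, specificity, decile calibration,
    feature importance), a sequential operating-room/PACU schedule
    simulator with an exhaustive-permutation oracle, and a chi-square
    comparison of historic versus risk-resequenced after-hours frequencies.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    glmnet,
    ranger,
    xgboost (>= 3.0),
    jsonlite,
    yaml,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
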