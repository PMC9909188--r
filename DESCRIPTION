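Package: rtnscreen
Title: Multimodal Response-to-Name Analytics for Early Autism Screening
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Computes response-to-name (RTN) latency and duration features
    from name-call event streams and per-frame face-detection records,
    estimates head yaw from 68 facial landmarks, applies rule-based ordinal
    scoring and joint two-procedure ASD classification under stratified
    10-fold cross-validation, and evaluates results with a diagnostic
    statistics suite (sensitivity/specificity, Mann-Whitney AUC with DeLong
    comparison of correlated ROC curves, Kruskal-Wallis with Dunn/Bonferroni
    post-hoc tests, Cronbach's alpha, Pearson chi-square). Includes a
    calibrated synthetic-cohort generator so the full pipeline is testable
    without video data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    methods,
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
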