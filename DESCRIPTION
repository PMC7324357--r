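Package: deltap
Title: Validation Toolkit for the DELTA-P Lung-Cancer Prediction Score in
    Lambert-Eaton Myasthenic Syndrome
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to score Lambert-Eaton myasthenic syndrome (LEMS) patients
    on the six-item DELTA-P clinical prediction score and its five-item DLTA-P
    variant, estimate per-score small-cell lung cancer (SCLC) risk with Wilson
    intervals, run the accompanying univariable (Fisher exact, Mann-Whitney),
    multivariable (logistic regression with Wald intervals) and survival
    (Kaplan-Meier, log-rank) statistics, analyse score discrimination via
    empirical ROC curves with DeLong variance and paired/independent AUC
    comparisons, derive score-stratified PET/CT tumour-screening schedules,
    and simulate synthetic LEMS cohorts calibrated to published group-level
    summaries for end-to-end pipeline testing.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    survival,
    pROC,
    optparse
Config/testthat/edition: 3
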