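Package: crmpred
Title: Predicting Developmental Enhancer Activity from Chromatin
    Accessibility, Nascent Transcription and Pol II Occupancy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies ATAC-seq, PRO-seq and Pol II ChIP-seq signal at
    peak calls intersected with tested cis-regulatory modules (CRMs),
    labels CRM enhancer activity against a basal-promoter reporter
    baseline, and evaluates logistic classifiers and linear regressors of
    activity by repeated stratified cross-validation with ROC,
    precision-recall and hold-out R-squared metrics. Includes BED and
    bedGraph interval/signal arithmetic built on IRanges run-length
    encodings, promoter-overlap stratification of CRMs, and a fully
    ground-truthed synthetic data generator emulating the statistical
    structure of whole-embryo regulatory genomics data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    IRanges,
    S4Vectors,
    graphics,
    grDevices,
    jsonlite,
    methods,
    stats,
    utils,
    yaml
Suggests:
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
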