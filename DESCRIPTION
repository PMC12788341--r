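Package: telemci
Title: Telematics-Based Classification of Pre-MCI/MCI in Older Drivers
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Trip-level feature construction from in-vehicle sensor streams,
    an L1-penalized random-intercept logistic model tuned by driver-grouped
    cross-validation, post-selection refitting with Wald and odds-ratio
    summaries, two-level (trip and driver) ROC evaluation with a driver
    bootstrap, and repeated grouped-cross-validation stability selection.
    Includes a synthetic cohort and sensor-stream generator that emulates a
    naturalistic driving study of older drivers, so the full pipeline can be
    exercised and validated end to end without access to participant data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    glmnet,
    pROC,
    lme4
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
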