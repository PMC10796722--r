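Package: crashrelm
Title: Rare Events Logistic Regression for Fatal Crash Risk
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Estimation and evaluation tools for modelling very rare binary
    outcomes such as fatal traffic crashes, where ordinary logistic
    regression underestimates event probabilities.  Implements choice-based
    (endogenous) subsampling that retains all events, the prior correction
    of the intercept, weighted maximum likelihood with case-control
    weights, a finite-sample coefficient bias correction, and a
    second-order correction of predicted probabilities.  An evaluation
    harness provides threshold classification rates, ROC curves with
    trapezoidal AUC, stratified K-fold cross-validation and event-ratio
    sweeps.  A synthetic data generator emulates a state-wide
    driver-vehicle crash census with categorical risk factors and a
    calibrated event rate, so the whole design can be exercised end to end
    without access to confidential crash records.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
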