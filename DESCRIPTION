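Package: pursuitrisk
Title: Dual Logistic Modelling of Pre-Season Risk Factors for Symptomatic Sports Concussion
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Simulates circular-pursuit eye-tracking records and athlete cohorts,
    extracts smooth-pursuit performance metrics (radial/tangential gaze error,
    phase lag, horizontal and vertical gain) with automated record screening,
    assembles the concussion analysis sample by symptom-burden classification
    and participant-flow exclusions, and fits two parallel risk models for a
    significant post-concussion symptom burden: a sequential domain-wise
    logistic selection with p < 0.10 retention feeding a summary model, and an
    elastic-net penalized logistic regression (coordinate descent, tenfold
    cross-validation, BIC/deviance-ratio lambda selection) refit by plain
    maximum likelihood. Both the logistic fitter (IRLS with Wald inference)
    and the elastic net are implemented from first principles; models are
    compared by pseudo R-squared, misclassification and ROC AUC.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    signal,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    glmnet,
    pROC,
    withr,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
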