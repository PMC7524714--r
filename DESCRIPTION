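Package: pelvisop
Title: Sagittal Pelvic Orientation from Biplanar Radiographs and
    Prediction of the Postoperative Standing Pelvic Tilt
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools to measure the sagittal orientation of the pelvis (SOP)
    by rigid 3D/2.5D registration of a landmarked pelvis model to two
    orthogonal radiograph-like projections, to evaluate the measurement
    accuracy with a controlled phantom protocol, and to predict the
    postoperative standing SOP after total hip arthroplasty from
    preoperative biometric, morphological and functional parameters using
    L1-penalised (LASSO) linear regression with leave-one-out
    cross-validation and the one-standard-error rule. Includes pelvic
    reference-plane construction, morphological parametrisation, a
    synthetic-data generator for cohorts and phantom views, and a
    range-of-motion cup safe-zone analysis under pelvic-tilt uncertainty.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    graphics
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    glmnet
Config/testthat/edition: 3
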