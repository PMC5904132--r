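Package: rhenet
Title: Rhythm-Entropy Classification and Time-Varying Directed Networks for Single-Trial EEG
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Single-trial error-versus-correct EEG analysis at the cortical level:
    weighted minimum-norm source estimation from scalp epochs, rhythm-entropy
    features over the theta, alpha and beta bands, R-squared discriminative
    dipole selection with back-projection, class-balanced RBF support vector
    machine classification under leave-one-out cross-validation, and
    time-varying directed connectivity via Kalman-fitted adaptive multivariate
    autoregressive models with the adaptive directed transfer function and
    phase-randomization surrogate significance testing. Includes a synthetic
    scalp-EEG generator with known ground truth (active dipoles, per-class
    band-power proportions, directed couplings) for end-to-end validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    signal,
    e1071,
    MASS,
    jsonlite,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    pROC
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
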