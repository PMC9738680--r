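Package: hmdrppg
Title: Remote Heart Rate Estimation from Head-Mounted-Display Facial Regions
Version: 0.1.0
Authors@R:
    person("Tiago", "Ferreira", email = "tiago.ferreira@example.org",
           role = c("aut", "cre"))
Description: Tools for estimating heart rate from the facial regions visible
    to the cameras of a virtual-reality head-mounted display (the two eyes
    and the lower face). Provides a synthetic face-video generator with a
    known pulsatile skin-colour signal, a landmark-driven region-of-interest
    extractor with threshold stabilization and an optional causal Eulerian
    motion magnification stage, a spatio-temporal feature-image constructor
    with an FFT band-pass and a depthwise-separable regression network, a
    meta-learning estimator built from a convolutional encoder, a
    bidirectional LSTM and an ordinal output layer with a synthetic-gradient
    generator for transductive adaptation, photoplethysmogram-to-BPM
    conversion by peak detection, and the standard evaluation metrics
    (ME, SD, RMSE, MAPE, Pearson correlation).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
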