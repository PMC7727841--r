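Package: catchsense
Title: Wrist-Worn Sensor Simulation and Convolutional Catch/Drop Classification
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: End-to-end pipeline for detecting the outcome of pass-receiving
    attempts (catch versus drop) from two wrist-worn multisensor wearables.
    Provides a synthetic attempt simulator with a four-phase catch motion
    (starting pose, positioning, impact, post-impact), event-triggered
    acquisition with an absolute-acceleration threshold, multirate linear
    resampling into a fixed 18,400 x 20 network input, a one-dimensional
    convolutional neural network with squeeze-and-excitation blocks trained
    with a Ranger-style optimizer, and a stratified cross-validation and
    channel-ablation evaluation harness.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Rcpp,
    stats,
    utils,
    grDevices,
    graphics,
    jsonlite,
    yaml
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
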