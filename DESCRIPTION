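Package: segnet
Title: Modulatory-Feedback Network for Attentional Figure-Ground Segmentation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A biologically constrained model of the primate ventral stream
    for attention-conditioned scene segmentation. A driving feedforward
    convolutional hierarchy (model areas V1m to FCm) classifies the objects
    in a 56x56 texture scene, and a gated, purely modulatory feedback
    pathway mirrors it back to pixel resolution: feedback units obey
    b = max(0, a * (z + beta)) and propagate c = b - a, so feedback can
    scale feedforward activity but never drive silent units. The package
    generates SegMNIST-style stimuli (oriented-texture backgrounds,
    texture-defined squares and rectangles, procedural digit glyphs) with
    ground-truth masks, trains the two pathways in two phases (multi-label
    classification, then attention-conditioned segmentation with the
    feedforward weights frozen), and simulates time-stepped activity
    propagation to extract figure/edge/ground response time-courses,
    figure-ground modulation and space-time profiles.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    signal,
    Rcpp
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    png,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
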