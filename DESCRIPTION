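Package: clickchain
Title: Detection, Unsupervised Clustering and Neural-Network Classification
    of Echolocation Clicks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: A desk-scale passive acoustic monitoring pipeline for impulsive
    underwater signals such as odontocete echolocation clicks. Provides a
    calibrated WAV streaming layer, a generic band-pass energy detector with
    peak-to-peak received-level thresholding and duration gating, two-phase
    unsupervised discovery of signal classes by Chinese Whispers clustering
    on correlation-similarity networks, encounter-aware training-set
    assembly, a multilayer-perceptron classifier operating on individual
    detections or five-minute binned averages, and evaluation tools
    (confusion matrices, precision/recall threshold sweeps, bin-level
    "none" accounting). A synthetic-scene simulator generates audio with
    known ground truth so the entire pipeline can be exercised and validated
    without field recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    data.table,
    jsonlite,
    Rcpp,
    signal,
    stats,
    utils,
    graphics,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    igraph,
    mclust,
    yaml
Config/testthat/edition: 3
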