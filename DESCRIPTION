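Package: pulvinet
Title: Gated Thalamocortical Skip Connections in Convolutional Vision Models
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements a small hierarchical convolutional vision model with a
    pulvinar-inspired long-range skip pathway (a learned early-to-late
    projection with squeeze-and-excitation style gain gating and per-channel
    convex fusion), together with matched control architectures, contrast
    invariance (S) and gain-linearity (HL) representational metrics,
    regularized training objectives, a near-threshold 1/f-noise contrast
    detection simulator, signal-detection analysis (d-prime, criterion,
    psychometric curves, stimulus-grid and quadrant summaries), and
    outcome-conditioned layer activation probes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    png,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
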