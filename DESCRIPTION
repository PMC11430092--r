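Package: dynfc
Title: Recurrent Brain-State Dynamics and Adaptive Thresholding of
    Amplitude-Envelope Functional Connectivity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for studying time-varying functional connectivity in
    parcel-level electrophysiological recordings. Converts parcel time
    series into orthogonalized amplitude envelopes, fits Gaussian hidden
    Markov models with information-criterion state-count selection, and
    derives temporal (fractional occupancy, mean lifetime, mean interval,
    transition probabilities) and spatial (state-wise within- and
    between-network connectivity, transition magnitudes) features of the
    decoded brain states. Includes an adaptive disparity-filter backbone
    with bootstrap median normalization and golden-section threshold
    optimization, exact Mann-Whitney U group comparisons with
    rank-biserial effect sizes and false-discovery-rate control, and a
    synthetic cohort generator with known Markovian ground truth for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    rlang,
    jsonlite,
    signal,
    car,
    ggplot2,
    stats,
    utils,
    tools
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
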