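Package: tusplast
Title: Whole-Brain Modeling of Ultrasound-Induced Plasticity in High-Order Interactions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to study how focal neuromodulation reshapes high-order
    functional interactions across the brain. Implements the Gaussian
    minimum-mutual-information integrated information decomposition of pairs
    of regional time series into sixteen atoms, including persistent
    redundancy and persistent synergy; structural communication models
    (streamline distance, shortest-path efficiency, search information,
    network communicability); a heterogeneous Stuart-Landau (Hopf)
    whole-brain simulator with a stimulation-intensity parameter; two-stage
    calibration of global coupling and regional heterogeneity against
    functional connectivity and Kuramoto synchrony; permutation-based
    regional contrasts and stimulation-intensity sweeps; and a synthetic
    cohort generator (region tables, distance-ruled connectomes,
    ground-truth BOLD-like cohorts) so the full pipeline runs with known
    ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Matrix,
    Rcpp,
    igraph,
    jsonlite,
    signal,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
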