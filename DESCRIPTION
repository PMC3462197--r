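Package: commod
Title: Stochastic Generation and Calibration of Commuting Origin-Destination Networks
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Generates commuting origin-destination matrices from per-unit
    in/out commuter margins with a single-parameter stochastic allocation
    model using exponential distance decay. Includes the common part of
    commuters (CPC, Sorensen-index) goodness-of-fit statistic, grid-search
    calibration of the distance-decay parameter, a power-law scaling of the
    parameter with the average surface of the geographic units, a
    cross-validation harness for that law, radiation and margin-based
    modified radiation comparator models, a uniform-random baseline, and a
    synthetic case-study generator so the whole pipeline is testable without
    external census data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
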