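Package: fretburst
Title: Burst Analysis of Single-Molecule FRET Photon Streams with
    Photon-by-Photon Hidden Markov Modeling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Confocal solution-based single-molecule FRET analysis for
    diffusing molecules under pulsed interleaved excitation: photon-stream
    simulation with full ground truth, all-photon burst search against a
    windowed background estimate, apparent FRET efficiency and stoichiometry,
    donor-only/acceptor-only filtering, leakage/direct-excitation/gamma
    correction factors, multi-parameter photon-by-photon hidden Markov
    modeling with exact interval-resolved EM, Viterbi dwell segmentation and
    ICL/BIC model selection, burst variance analysis against the shot-noise
    expectation, and a geometric interpretation layer (Forster distance,
    tether radius, local concentration, steady-state anisotropy).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    dplyr,
    generics,
    ggplot2,
    purrr,
    rlang,
    stats,
    tibble,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
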