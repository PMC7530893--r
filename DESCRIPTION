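Package: plstates
Title: Leading-Eigenvector Dynamics of BOLD Phase-Locking States
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for characterizing recurrent phase-locking (PL) states in
    band-limited BOLD signals. Implements the leading-eigenvector dynamics
    analysis (LEiDA) pipeline: zero-phase Butterworth band-pass filtering,
    Hilbert-transform instantaneous phases, per-frame phase-locking matrices
    reduced to leading eigenvectors, k-means detection of recurrent PL states
    across a range of partition models, and per-subject occupancy, lifetime and
    transition-probability profiles compared between groups with stratified
    (gender-restricted) permutation tests and per-model FDR control. A second,
    static arm computes full-scan Pearson functional connectivity and contrasts
    groups with the network-based statistic (suprathreshold connected
    components, FWER by max-component-size permutation). A synthetic-cohort
    generator with planted Markov-switching PL states provides ground truth for
    every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    signal,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
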