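Package: clocksync
Title: Phase Synchronization Analysis of Single-Cell Circadian Clocks
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for studying phase synchronization of cellular circadian
    clocks in Neurospora crassa microfluidic experiments. Implements
    deterministic quorum-sensing and cell-contact clock-network models for
    coupled "giant cells", ensemble Metropolis-Hastings parameter
    identification against fluorescence trajectories, Hilbert-phase
    extraction and Kuramoto order-parameter synchronization statistics,
    stochastic Kuramoto phase-model simulation and fitting, trajectory
    clustering and density-dependence tests, a diffusion-based bound on the
    size of the quorum-sensing signal molecule, and a synthetic-data
    generator emulating microwell single-cell fluorescence recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    readr,
    ggplot2,
    generics,
    MASS,
    stats
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
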