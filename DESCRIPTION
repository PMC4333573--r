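Package: boldsync
Title: Time-Varying Phase Synchronization of Resting-State BOLD Signals
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Analysis of time-varying phase synchronization in region-averaged
    resting-state BOLD signals. Provides narrowband filtering and analytic-phase
    extraction, the Kuramoto order parameter and phase-locking value (PLV)
    statistics with phase-randomized surrogate null models, binary
    synchronization tensors decomposed by nonnegative canonical polyadic
    factorization with DIFFIT component selection for temporal community
    detection, Kuramoto phase-oscillator simulations on weighted structural
    connectomes (heterogeneous, shuffled-connectivity, homogeneous, and
    stochastic variants), and a grid-sweep harness that scores model-data
    agreement via Kullback-Leibler similarity, PLV-matrix correlation, and
    permutation-null community matching. Includes synthetic generators for
    modular connectomes and transiently synchronized oscillatory signals with
    planted ground truth.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    signal,
    jsonlite,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    igraph,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
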