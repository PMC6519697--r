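Package: mrbranch
Title: Branching Networks and Subsampling-Invariant Estimation of Neural
    Spike Propagation
Version: 0.1.0
Authors@R:
    person("mrbranch", "developers", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Simulates branching networks with immigration as a minimal
    model of cortical spike propagation, and estimates the branching
    ratio m and the intrinsic network timescale tau from (heavily
    subsampled) spike recordings using the multistep-regression
    estimator, whose geometric slope decay is invariant under spatial
    subsampling.  Includes the conventional lag-one estimator for
    comparison, parametric-bootstrap confidence intervals, stationarity
    and fit-adequacy consistency checks, validation statistics
    (inter-spike intervals, Fano factors, activity distributions,
    neuronal avalanches with model-likelihood comparison, spike-count
    cross-correlations, autocorrelation functions), a single-extra-spike
    perturbation suite with closed-form susceptibility and
    external-input fraction, and an end-to-end pipeline that matches
    asynchronous-irregular, reverberating, and near-critical surrogate
    models to a recording.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    data.table,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
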