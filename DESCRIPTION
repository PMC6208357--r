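Package: splitkl
Title: Sampling Bias of Operator-Splitting Langevin Integrators via Shadow-Work KL Estimators
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Constructs finite-timestep Langevin integrators from operator-splitting
    strings over the R/V/O substeps (position drift, velocity kick,
    Ornstein-Uhlenbeck velocity randomization), with exact per-trajectory
    shadow-work accounting for symmetric (palindromic) splittings. Quantifies the
    timestep-induced sampling bias as a Kullback-Leibler divergence from the
    equilibrium density, in full phase space and in the configuration-space
    marginal, using three estimators: a near-equilibrium work estimator (the
    halved difference of two shadow-work averages), an asymptotically exact
    nested Monte Carlo estimator with a Jensen-inequality upper bound and a
    two-level jagged bootstrap, and an exact histogram/quadrature reference for
    one-dimensional systems. Also provides generalized hybrid Monte Carlo
    (GHMC) acceptance-rate analysis and experiment drivers for timestep sweeps,
    collision-rate sweeps, sandwich validation and stability scans.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
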