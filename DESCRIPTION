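Package: OnOffDynamics
Title: On-Off Cortical State Dynamics, Poisson HMM Inference, and the
    Spatial Structure of Noise Correlations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for studying how bistable On-Off population dynamics
    shape correlated variability in columnar cortical recordings. Provides
    a synthetic generator of laminar spike-count sessions with a shared
    two-state Markov population state; a shared-latent-state Poisson hidden
    Markov model (HMM) with EM fitting, cross-validated phase-number
    selection, Viterbi decoding and transition-rate conversion; a bistable
    rate-adaptation column model and its 2-D lattice network with diffusive
    coupling; the reduced binary-unit (Glauber-type) network with an exact
    master-equation solver and moment equations; closed-form predictions of
    Fano factors and distance-dependent noise correlations; and an
    empirical statistics pipeline (noise correlations, Fano factors,
    modulation indices, cortical-distance conversion, distance regressions,
    correlation-length fits, decile comparisons).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    jsonlite,
    data.table,
    deSolve,
    minpack.lm,
    igraph,
    tools,
    S4Vectors,
    BiocGenerics,
    SummarizedExperiment
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'AllGenerics.R'
    'AllClasses.R'
    'RcppExports.R'
    'synthetic-sessions.R'
    'onoff-hmm.R'
    'column-model.R'
    'lattice-network.R'
    'binary-network.R'
    'theory.R'
    'corr-stats.R'
    'workbench.R'
    'io.R'
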