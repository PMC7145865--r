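Package: elsnet
Title: Brain-Network Connectivity, Attention Bias and Mediation Analysis
    for Early-Life Stress Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for relating early-life stress to depression through
    resting-state brain-network connectivity and attentional bias.
    Computes within- and between-network connectivity statistics from
    ROI time series over a node-to-network partition, screens
    connectivity measures against behavioral scores with
    covariate-adjusted partial correlations and Benjamini-Hochberg FDR
    control, estimates brain-behavior prediction accuracy with
    balanced-fold cross-validated linear support vector regression,
    fits simple mediation models with bias-corrected bootstrap
    confidence intervals for the indirect effect, and scores dot-probe
    attention-bias experiments from trial-level reaction times. A
    synthetic-data generator produces block-covariance ROI time series,
    behavioral tables with planted mediation structure, and dot-probe
    trial logs so the full pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    e1071,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
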