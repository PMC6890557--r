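Package: plsconn
Title: Multi-Label Estimation of Behavioral Traits from Functional
    Connectivity with Partial Least Squares
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simultaneous estimation of multiple cognitive, behavioral and
    demographic variables from resting-state functional connectivity using
    multi-response partial least squares regression (SIMPLS).  Provides
    construction of full-correlation and ridge-regularized
    partial-correlation network matrices from region-of-interest
    time-series, upper-triangle edge-feature vectorization, cross-validated
    multi- and single-label estimation with optionally family-aware folds,
    permutation significance of estimation accuracies and of fold-averaged
    edge weights, affinity-propagation clustering of regions into networks,
    network-level contribution summaries, an RBF-kernel PLS variant, and a
    synthetic-data generator with planted effect edges for end-to-end
    validation of the whole pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    MASS,
    pROC,
    mixOmics
Config/testthat/edition: 3
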