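Package: eegconn
Title: Resting-State EEG Functional Connectivity and Graph Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: End-to-end analysis of multichannel resting-state EEG
    functional connectivity for two-group comparisons. Fits multivariate
    autoregressive (MVAR) models with AIC order selection and validation,
    derives the directed transfer function (DTF) from the model transfer
    matrix, estimates the imaginary part of coherency from Welch
    cross-spectra, binarizes band-averaged connectivity matrices by the
    minimum-connected-component (MCC) rule, computes global graph metrics
    (diameter, global efficiency, transitivity), and compares groups with
    Shapiro-Wilk and Wilcoxon rank-sum tests. Includes a synthetic-cohort
    generator with fully known VAR ground truth, a preprocessing chain
    (zero-phase high-pass FIR, sliding-window line-noise removal, ICA with
    rule-based artifact-component flagging and back projection), and a
    configurable pipeline runner.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    igraph,
    signal,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
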