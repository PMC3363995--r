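Package: neurodi
Title: Directed Information Measures of Effective Connectivity for Trial-Based Neural Time Series
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Model-free estimation of directed (causal) information flow between
    trial-based neural time series. Implements directed information, time-lagged
    directed information, and the modified time-lagged directed information (MDI)
    upper bound computed across trials, with Gaussian closed-form, histogram, and
    adaptive-partitioning mutual-information estimators; model-free order selection
    by the Cao false-nearest-neighbour criterion; trial-shuffle and time-shuffle
    permutation nulls with empirical p-values and Benjamini-Hochberg false discovery
    rate control; a time-domain Granger causality (Geweke index) comparator; seeded
    generators for five benchmark systems (multi-order linear and sigmoid-coupled
    nonlinear Gaussian autoregressive pairs, linear mixtures, common-source models,
    and delay-coupled Lorenz oscillators); and an end-to-end pairwise
    effective-connectivity pipeline with band-pass filtering and delimited-text I/O.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    signal,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
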