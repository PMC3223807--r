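Package: funcEquiv
Title: Functional Equivalence and Collapse Prediction in Community Time Series
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Discrete Bayesian-network tools for detecting functional collapse in
    ecological community biomass time series and transferring models between
    systems. Implements Cooper-Herskovits (K2) and BIC network scoring with a
    greedy K2 structure search, bootstrap filter and wrapper feature selection
    against a binary collapse class, a simulated-annealing search for
    functionally equivalent species between two communities, and a dynamic
    Bayesian network with a binary latent regime node for one-step-ahead
    biomass prediction and regime-shift detection. A synthetic multi-region
    community generator with known ground truth supports end-to-end evaluation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    S4Vectors,
    SummarizedExperiment,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'RcppExports.R'
    'biomass-table.R'
    'dag.R'
    'dbn-em.R'
    'dbn-predict.R'
    'dbn.R'
    'discretize.R'
    'equivalence.R'
    'feature-selection.R'
    'funcEquiv-package.R'
    'inference.R'
    'k2-search.R'
    'pipeline.R'
    'scores.R'
    'synthetic.R'
    'utils.R'
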