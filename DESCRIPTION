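Package: scnet
Title: Structural Covariance Network Analysis of ROI Cortical Thickness
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds and compares structural covariance networks from
    region-of-interest cortical thickness tables. Provides a synthetic
    crossover-cohort generator with modular between-region covariance,
    across-subject Pearson correlation matrices with Benjamini-Hochberg
    FDR binarization, binary-graph metrics (clustering, characteristic
    path length, global/local efficiency, degree, nodal efficiency,
    betweenness), small-worldness against degree-preserving
    Maslov-Sneppen random references, paired condition-label permutation
    inference with nodal FDR correction, and summary-statistic
    demographics tests for crossover sleep-restriction designs.
License: MIT
Encoding: UTF-8
Imports:
    stats,
    utils,
    tools,
    Rcpp,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    igraph
Config/testthat/edition: 3
RoxygenNote: 7.3.3
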