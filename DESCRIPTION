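Package: randnat
Title: Natural versus Random Protein Classification from Structural Descriptors
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to ask whether natural proteins can be told apart from random
    polypeptides on the basis of simple structural descriptors. Provides
    extraction of eleven structure-related variables from PDB coordinate files
    (net charge, residue volume, solvent-accessible surface area by
    Shrake-Rupley sampling, Kabsch-Sander style secondary-structure content and
    surface hydrophobicity), a uniform random-sequence generator with a
    pluggable novelty filter, a synthetic feature-table simulator parameterized
    by published per-class moments, tail-quantile outlier filtering with class
    balancing, a nonparametric statistical battery (Shapiro-Wilk, Wilcoxon
    rank-sum, Fligner-Killeen), and an Evolutionary Neural Network Algorithm
    (ENNA): a genetic algorithm over binary variable masks scored by the
    10-fold cross-validated misclassification rate of a two-hidden-layer
    sigmoid multilayer perceptron.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    bio3d,
    jsonlite,
    Rcpp,
    seqinr,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
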