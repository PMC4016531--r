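Package: triphase
Title: Two-Phase Kernel Learning for Heterotrimeric Protein Complex Prediction
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Predicts heterotrimeric protein complexes (complexes of exactly
    three distinct proteins) from a weighted protein-protein interaction
    network. Candidate triplets of connected proteins are described by seven
    graph-derived features (internal and neighboring interaction weights and
    protein domain counts) and a 0/1 domain composition kernel. A first
    max-margin classifier is trained on a precomputed Gram matrix; its
    discriminant values over each triplet and its neighboring triplets are
    summarised into four additional features, and a second classifier (support
    vector machine or sparse-Bayesian relevance vector machine) is trained on
    the combined 11-dimensional representation. Includes readers for weighted
    interaction tables, domain annotations and complex catalogues, a synthetic
    benchmark generator with planted complexes, repeated stratified
    cross-validation, and command-line entry points.
License: MIT
Encoding: UTF-8
Imports:
    kernlab,
    jsonlite,
    optparse,
    stats,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0),
    e1071
Config/testthat/edition: 3
RoxygenNote: 7.3.3
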