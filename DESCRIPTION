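Package: fmsm
Title: Factored miRNA Similarity Models for Disease Biomarker Ranking
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Ranks candidate microRNA (miRNA) biomarkers for human diseases
    from a sparse binary miRNA-disease association network. A factored
    item-similarity model learns an miRNA-miRNA similarity matrix as the
    product of two latent factor matrices by stochastic gradient descent on
    a squared-error loss with negative sampling, and the learned scores are
    combined with miRNA expression similarity (Pearson correlation over
    tissue expression profiles), MeSH-based disease semantic similarity and
    Gaussian interaction-profile kernel similarity. Includes local
    leave-one-out and repeated k-fold cross-validation with per-fold kernel
    recomputation, a similarity-ablation experiment, and a synthetic data
    generator with planted block structure for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    data.table,
    graphics,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
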