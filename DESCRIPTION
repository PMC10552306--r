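Package: pathnn
Title: Pathway-Sparsified Neural Networks for Exome-Based Genome Interpretation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Gene-centric mutational-load encoding of annotated exome variants
    and a family of small neural-network architectures of graded expressivity
    (logistic-regression head, pathway-sparsified hidden layer, dense hidden
    layer, and an all-linear control) built on a shared per-gene module.
    Includes knowledge-based, random, L1-learned and RigL-learned sparsity
    masks for the gene-pathway layer, focal-loss training with Adam, repeated
    stratified cross-validation with the variance-corrected resampled t-test,
    an ensemble of randomly sparsified networks, additive and random-forest
    baselines, and a case-control cohort simulator that plants additive,
    magnitude-epistatic and reciprocal-sign-epistatic (XOR-like) genetic
    architectures so that the mapping between architecture expressivity and
    detectable epistasis type can be studied end to end.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    Rcpp,
    Matrix,
    data.table,
    jsonlite,
    glmnet,
    ranger
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr,
    optparse,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
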