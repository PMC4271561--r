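Package: mrrcc
Title: Meta-Sample Regularized Robust Coding Classification of Gene
    Expression Profiles
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Molecular cancer (sub)class prediction from gene-expression
    matrices by coding each test sample against a dictionary of per-subclass
    meta-samples. Meta-samples are left singular vectors of each subclass's
    training submatrix; a test sample is coded against the concatenated
    dictionary under a regularized robust loss in which per-gene logistic
    weights downweight outlier genes, solved by an iteratively reweighted
    scheme with either an l2 (ridge) or l1 (lasso) coefficient penalty. The
    predicted subclass minimizes the weighted block-restricted reconstruction
    residual. Includes the evaluation harness (stratified and nested
    cross-validation over the number of meta-samples, balanced train/test
    division, Kruskal-Wallis gene filtering), a latent-factor synthetic-data
    generator with outlier-gene contamination, plain-text model
    serialization, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
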