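Package: mlsa
Title: Modular Latent Structure Analysis for High-Throughput Data
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Exploratory estimation of modular latent structures in
    feature-by-condition matrices such as gene expression data. Modules are
    low-dimensional subspaces of condition space that explain a subset of the
    rows very well; each module is fitted by an EM-like iteration of weighted
    singular value decomposition, membership is decided by a conservative
    false-discovery-rate rule on projection lengths, module dimensionality is
    grown by forward selection with an adjusted hypergeometric overlap test,
    and a series of modules is discovered by deflation (member removal or
    residual retention). Discovered factors are assembled into a sparse
    overall factor model with loadings filled by per-row regression or by
    lasso with BIC model selection. A simulation framework generates modular
    and global-sparse latent-structure datasets and scores factor recovery by
    a two-step squared-multiple-correlation protocol.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    graphics,
    methods,
    Matrix,
    glmnet,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
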