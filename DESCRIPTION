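Package: scevlink
Title: Linking Chromatin Accessibility to Single-Cell Expression Variability
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A testing pipeline for whether chromatin accessibility explains
    single-cell expression variability (scEV) in paired scATAC-seq/scRNA-seq
    multiome data. Per-gene expression is predicted from accessibility peaks
    with seven models (k-nearest neighbours, lasso with BIC model selection,
    peak-fusion lasso, gradient-boosted trees, a small feed-forward neural
    network, the unsupervised gene activity score, and a local-window lasso),
    per-gene expression variability is scored with two detectors (standardized
    variance after a loess mean-variance fit, and signed distance to a 3-D
    spline of dropout rate, log mean and log CV), and prediction performance is
    compared between highly variable genes and the rest with one-sided
    Wilcoxon, Spearman and Fisher tests plus a matched-mean control. A
    synthetic paired-multiome generator with known accessibility-to-expression
    coupling provides ground truth so every stage is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    methods,
    stats,
    utils,
    glmnet,
    xgboost,
    irlba,
    uwot,
    yaml,
    GenomicRanges,
    IRanges,
    S4Vectors
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr,
    Seurat
Config/testthat/edition: 3
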