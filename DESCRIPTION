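Package: senpred
Title: Single-Cell Senescence Classification in Principal-Component Space
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Trains and applies classifiers of fibroblast senescence state
    (early-proliferative, early-senescent, deeply-senescent) on single-cell
    RNA-seq data. Provides 10x-style count matrix input/output, per-cell QC and
    filtering, log-normalization, highly variable gene selection, PCA, shared
    nearest-neighbor Louvain clustering and Wilcoxon marker testing; a mixture
    discriminant analysis core (shared-covariance Gaussian subclass mixtures fit
    by EM) alongside SVM-RBF, KNN and binomial GLM backends with stratified
    cross-validation; reference-to-query projection with a posterior rejection
    threshold; per-donor senescent-cell burden estimation with age correlation;
    and a deterministic negative-binomial synthetic data generator so the whole
    pipeline runs without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    igraph,
    e1071,
    class,
    jsonlite,
    stats,
    utils,
    methods
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse
Config/testthat/edition: 3
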