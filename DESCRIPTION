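Package: crcmods
Title: Module-Based Consensus Subtyping of Colorectal Cancer Expression Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Unsupervised discovery and validation of colorectal cancer gene
    expression subtypes from multi-cohort collections. Genes are grouped into
    co-expression modules by complete-linkage hierarchical clustering with a
    dynamic-hybrid tree cut, screened for cross-dataset robustness, and
    summarized as per-sample meta-genes (module medians). Samples are
    clustered on meta-genes with a resampling-based consensus distance and
    subtypes are defined on core samples by dendrogram pruning. A regularized
    multiclass linear discriminant classifier assigns new samples to
    subtypes, and sparse subtype signatures are extracted by multinomial
    elastic-net regression. Subtypes are matched across independent cohorts
    via correlations of one-versus-all moderated t profiles combined with
    classifier cross-prediction, and characterized by differential meta-gene
    expression, marker enrichment against the population baseline,
    permutation-based gene set enrichment, and survival models (IQR-
    standardized stratified Cox, truncated pairwise log-rank, additive
    multivariate Cox). A synthetic-data generator plants modules, subtypes,
    batch effects, markers and survival so every stage is testable by
    recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    survival,
    glmnet,
    withr
Suggests:
    testthat (>= 3.0.0),
    limma,
    MASS,
    mclust,
    jsonlite
Config/testthat/edition: 3
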