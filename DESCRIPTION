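Package: scNMTF
Title: Joint Non-Negative Matrix Tri-Factorization of Single-Cell
    Expression with Molecular Interaction Networks
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Integrates a condition-specific single-cell expression matrix
    with four gene-gene molecular interaction networks (protein-protein,
    genetic, co-expression and metabolic) by jointly tri-factorizing all
    five matrices around a shared non-negative gene factor. Provides an
    SVD-initialized multiplicative-update solver, dispersion-based latent
    rank selection, gene-embedding geometry summaries (gene mapping
    matrices and cross-condition gene movement), hypergeometric cluster
    enrichment, a two-step disease-gene prediction procedure with
    movement-based ranking, validation statistics (one-sided rank-sum
    tests, resampling overlap significance, shortest-path proximity,
    BH-corrected pathway enrichment), and a synthetic study generator
    with planted gene modules and perturbed disease genes.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    igraph,
    S4Vectors,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
biocViews: SingleCell, Network, DimensionReduction, GeneExpression,
    NetworkInference, Clustering
RoxygenNote: 7.3.3
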