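Package: lmsproteo
Title: Proteogenomic Subtyping and Genomic Instability Scoring for Multi-Omic Tumor Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end analysis chain for tandem-mass-tag (TMT)
    proteogenomic tumor cohorts, built around soft-tissue leiomyosarcoma-style
    study designs. Provides TMT preprocessing (missingness filtering, KNN
    imputation, sample-loading normalization, internal reference scaling
    across plexes, and TMM median centering), consensus non-negative matrix
    factorization subtyping with cophenetic and silhouette rank selection,
    allele-specific copy-number instability scores (ploidy, whole-genome
    doubling, LOH, CIN, and the HRD-LOH/LST/TAI scar components),
    single-sample GSEA and hypergeometric over-representation testing,
    kinase-substrate activity inference from phosphosite fold changes,
    cis/trans copy-number-expression mapping, subtype-transfer
    classification, and Kaplan-Meier survival stratification. A synthetic
    cohort generator with planted ground truth makes every stage testable
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    cluster,
    survival,
    randomForest,
    jsonlite,
    Rcpp
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    mclust,
    edgeR,
    knitr,
    rmarkdown
Config/testthat/edition: 3
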