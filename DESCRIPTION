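Package: gliotam
Title: Discovery and Characterization of Scavenger-Receptor Macrophage
    Subpopulations in Glioma Single-Cell Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: An end-to-end, reproducible pipeline for subtyping
    tumor-associated macrophages in multi-sample glioma single-cell
    RNA-seq cohorts: count-matrix merging and log2(1+TPK) normalization,
    immune-panel restriction, PCA/UMAP embedding with marker-based cell
    typing, silhouette-selected k-means clustering of the macrophage
    compartment, empirical exact-permutation marker ranking, per-cell
    gene-signature scoring, gene set enrichment analysis with a
    continuous phenotype and phenotype permutation, paired
    macrophage-tumor cross-talk correlation, and bulk-expression
    survival analysis (Kaplan-Meier/log-rank and Cox proportional
    hazards). Ships a synthetic-cohort generator that plants discrete
    cell types, two opposed macrophage programs, sample-level genotype
    effects and a matched bulk survival cohort, so every stage is
    testable without access to patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    cluster,
    methods,
    jsonlite,
    stats,
    survival,
    tools,
    utils,
    uwot,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
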