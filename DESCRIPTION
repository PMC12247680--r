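Package: heartgrowth
Title: Stochastic Lineage Models and Single-Cell Tools for Juvenile
    Heart Growth in Ciona
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for studying cardiomyocyte-progenitor driven heart
    growth in the tunicate Ciona robusta. Provides a stochastic
    simulator of the undifferentiated-line (UL) division model in
    which self-renewing distal progenitor clusters emit midline cells
    that either elongate the UL or detach as myocardial precursors; an
    EdU pulse/chase labeling model with proliferative-index,
    division-rate and clone-census estimators; synthetic single-cell
    expression and assay-table generators with planted ground truth; a
    compact scRNA-seq processing pipeline (QC, normalization,
    regression/scaling, PCA, Louvain clustering, fixed-resolution
    sub-clustering, Wilcoxon marker ranking); a reference-correlation
    procedure for flagging contaminating blood cell clusters with a
    replicate-calibrated threshold, marker-overlap rescue and an
    abundance guard; and the assay statistics used for perturbation
    experiments (normalized UL counts, per-region EdU percentages,
    Fisher's exact morphology tests, paired heart-rate tests).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    igraph,
    jsonlite,
    methods,
    stats,
    utils
Suggests:
    mclust,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
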