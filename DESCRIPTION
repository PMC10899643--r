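Package: neutrotime
Title: Neutrophil Maturation Trajectories, Gene Modules and Cross-Species
    Alignment from Single-Cell Expression
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to order maturing neutrophils along a pseudotime
    trajectory, discretize the trajectory into expression bins, select
    maturation-associated genes with a spline association test, partition
    genes into modules and trajectory bins into maturation phases by
    dynamic-time-warping (DTW) hierarchical clustering with
    Kelley-Gardner-Sutcliffe cluster-number selection, rank transcription
    factors as candidate module regulators via scaled DTW similarity,
    align trajectories across species by cross-correlation lag, derive
    pan-species maturation signatures, and score bulk or pseudo-bulk
    samples by single-sample gene set enrichment (ssGSEA) and
    expression-matched module scores. Includes a negative-binomial
    synthetic-data generator with planted ground truth for end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    Matrix,
    methods,
    splines,
    stats,
    utils,
    graphics,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    mclust,
    limma
Config/testthat/edition: 3
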