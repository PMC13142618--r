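Package: glioprog
Title: Glial Multicellular Program Stratification for Single-Nucleus and
    Spatial Transcriptomics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A tested pipeline for stratifying Parkinson's disease donors
    into mutually exclusive glial multicellular programs (UPR-high,
    Reactive, Homeostatic) from single-nucleus RNA-seq and imaging spatial
    transcriptomics. Implements layered nucleus quality control (fixed
    thresholds, polynomial-residual outliers, consensus doublet voting,
    Gaussian-mixture heterotypic doublet removal), centered log-ratio
    compositional statistics with Mann-Whitney and Spearman tests,
    expression-matched gene-signature module scoring, Wilcoxon differential
    expression with magnitude tiers and dual-threshold overlap logic,
    donor classification rules, k-nearest-neighbor sample divergence, and
    Moran's I spatial autocorrelation on Delaunay neighbor graphs. Ships a
    seeded synthetic cohort generator that emulates the statistical
    structure the pipeline assumes, so every stage is testable end to end
    without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    matrixStats,
    mclust,
    deldir,
    FNN,
    jsonlite,
    methods,
    stats,
    utils,
    tools,
    withr
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
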