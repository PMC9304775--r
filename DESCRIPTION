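Package: scmntb
Title: Single-Cell Transcriptomic Clustering and Intercellular Signaling
    Analysis for the Developing Auditory Brainstem
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A tested re-implementation of a marker-driven single-cell
    RNA-seq analysis workflow for small dissociated-tissue datasets such as
    the early postnatal medial nucleus of the trapezoid body (MNTB):
    MAD-based cell quality control, detection-threshold gene filtering,
    pooled deconvolution size-factor normalization with log2-CPM
    conversion, LOESS mean-variance highly-variable-gene selection with a
    Spearman correlation filter, Ward hierarchical clustering with a
    minimum cluster size and iterative differential-expression-driven
    refinement, negative-binomial cluster contrasts with average-CPM fold
    changes, marker-based cell-type annotation with reporter-transcript
    validation, directional ligand-receptor summaries, and the imaging
    quantification arithmetic (percent positive area, volume fractions,
    Benjamini-Krieger-Yekutieli two-stage FDR) used for validation
    experiments. Includes a negative-binomial synthetic-data generator
    with planted markers, low-quality cells and doublets so every stage is
    testable against ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Matrix,
    methods,
    stats,
    utils,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    withr,
    mclust,
    scran,
    edgeR,
    jsonlite
Config/testthat/edition: 3
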