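Package: hypoxiaTME
Title: Hypoxia and Immune Microenvironment Analysis for Bulk, Single-Cell,
    and Spatial Transcriptomics
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for linking tumor hypoxia to immune-microenvironment
    remodeling across bulk, single-cell, and spatial transcriptomics.
    Implements single-sample gene-set scoring (a weighted Kolmogorov-Smirnov
    rank walk and a mean scaled-expression scorer) of a 15-gene hypoxia
    signature and arbitrary signatures; hexagonal-lattice tumor-boundary
    delineation on spatial slides (malignant core identification and
    layer-wise extrapolation into Mal, Bdy, and nMal regions); non-negative
    least-squares spot deconvolution, ALCAM-high macrophage gating, exhausted
    T-cell spot calling, and first-outer-circle co-localization testing;
    immunophenoscore computation from weighted category-averaged sample
    Z-scores; pseudotime trend testing with a multi-dataset
    transcription-factor consistency filter; association screens,
    immunotherapy-response contrasts, and maximally selected log-rank
    cutpoint survival stratification. Ships synthetic-data generators with
    full ground truth for parameter-recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    Matrix,
    S4Vectors,
    SummarizedExperiment,
    igraph,
    pracma,
    survival,
    splines,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr
Config/testthat/edition: 3
biocViews: Transcriptomics, Spatial, SingleCell, GeneExpression, Survival
RoxygenNote: 7.3.3
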