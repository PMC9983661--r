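Package: liberality
Title: Transcriptome Shannon Entropy as a Measure of Cellular
    Dedifferentiation
Version: 0.99.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Quantifies cellular dedifferentiation from bulk RNA-seq count
    matrices as the Shannon entropy of per-sample gene occupation rates
    ("liberality"): a differentiated tissue concentrates its transcriptome
    on few genes (low entropy), a dedifferentiating culture flattens it
    (high entropy). Provides validated count-matrix and sample-sheet
    import (TSV/CSV/MatrixMarket), a multi-hit mapping-rate QC check,
    plug-in and Miller-Madow entropy estimators with evenness and
    effective gene number, a from-first-principles linear-model slope
    t-test of entropy against extract dose or culture time, a seeded
    multinomial read-sampling simulator with a temperature-tempered Zipf
    expression model for generating realistic synthetic experiments,
    stacked occupancy bar charts and entropy scatter plots, and a
    command-line interface chaining simulate, entropy, test and plot.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    tools,
    Matrix,
    S4Vectors,
    SummarizedExperiment,
    ggplot2,
    rlang
Suggests: testthat (>= 3.0.0), jsonlite
Config/testthat/edition: 3
biocViews: Transcriptomics, GeneExpression, QualityControl, Software
RoxygenNote: 7.3.3
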