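Package: methylProgression
Title: Staged DNA Methylation Progression Analysis for Treatment-Resistant
    Prostate Cancer Models
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for tracking DNA methylome changes across staged disease
    models, built around methylation array beta values. Implements probe
    filtering, empirical-Bayes moderated-t differential methylation calling
    with FDR and delta-beta thresholds, Ward hierarchical clustering of
    samples, set algebra over differentially methylated probe (DMP) sets
    across a comparison scheme (common DMPs, direction switches, delta-beta
    concordance), genomic feature and CpG-island context composition,
    gene-level hyper:hypo net methylation scoring, promoter versus gene-body
    methylation-expression scenario classification, and a cell-free DNA
    biomarker stage: per-patient DMP-DMR overlap ratios, Spearman correlation
    with time to progression, and a probe-resampling null with a
    one-proportion z-test. A synthetic-data generator with known planted
    truth provides calibration and recovery surfaces for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    IRanges,
    GenomicRanges,
    SummarizedExperiment,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    limma,
    withr,
    yaml
Config/testthat/edition: 3
biocViews: DNAMethylation, DifferentialMethylation, Epigenetics,
    MethylationArray, GeneExpression, Software
RoxygenNote: 7.3.3
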