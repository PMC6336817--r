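Package: consensusMR
Title: Consensus Co-Expression Networks for Master Regulator Discovery in
    Neuroendocrine Tumors
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Identifies candidate master transcriptional regulators of poorly
    differentiated neuroendocrine tumors (NETs) from multi-cohort expression
    data. Implements per-cohort Wilcoxon rank-sum differential expression with
    Benjamini-Hochberg false discovery control and fold-change filtering,
    cross-cohort intersection of upregulated genes, consensus co-expression
    networks weighted by cross-cohort correlation counts with modularity-based
    community detection and weighted-degree ranking of transcription factors,
    per-sample sum-of-z gene-signature scoring (hypoxia and regulator-activity
    scores), genomic-interval utilities for peak-to-TSS assignment and peak-set
    overlap, and a three-filter co-factor cascade combining direct targets,
    motif genes and protein interactors. A synthetic multi-cohort simulator
    with planted ground truth supports end-to-end validation of every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    IRanges,
    GenomicRanges,
    SummarizedExperiment,
    igraph,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
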