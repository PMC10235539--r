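Package: scRegLoops
Title: Marker Specificity, Cell-Type Abundance, Expression Patterns,
    Regulon Activity and TF Regulatory Loop Mining for Single-Cell
    Transcriptomics
Version: 0.99.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: An in-depth mining toolkit for annotated single-cell
    transcriptomes of case/control tissue. Scores the cell expression
    specificity of genes (CESG, the ratio of expressing-cell fractions
    inside versus outside a cell type) to nominate novel cell-type
    markers; quantifies cell-type abundance across conditions as an
    observed/expected ratio (ACT); performs per-cell-type Wilcoxon
    rank-sum differential expression; extracts non-negative
    gene-expression patterns by seeded multiplicative-update NMF and
    scores their cell-type predictive power as an AUROC; computes
    regulon activity (RAS, a rank-based recovery-curve area) and
    regulon specificity (RSS, one minus the Jensen-Shannon divergence
    between the activity distribution and a cell-type indicator); and
    assembles cell-specific transcription-factor regulatory loops by
    hypergeometric overlap testing among pattern, regulon and DEG gene
    sets, with pathway annotation and graph export. A synthetic-data
    generator with fully planted ground truth (markers, DEGs, patterns,
    regulons, ternary loops) makes every stage testable end to end.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    S4Vectors,
    SummarizedExperiment,
    jsonlite,
    igraph
Suggests:
    testthat (>= 3.0.0),
    withr,
    xml2,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
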