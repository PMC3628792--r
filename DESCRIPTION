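Package: mircascade
Title: Knowledge-Based Enrichment Cascade for Candidate Regulator miRNAs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Multi-stage knowledge-based enrichment analysis that prioritizes
    candidate regulator microRNAs from a two-strain, two-treatment expression
    experiment. The cascade chains percentile-shift normalization and
    detection-flag filtering, dual-criteria differential-expression selection
    (exact Mann-Whitney rank tests, two-way ANOVA, fold-change thresholds,
    three-list Venn combination), hierarchical clustering of selected genes,
    hypergeometric Gene Ontology over-representation, position-weight-matrix
    promoter scanning with transcription-factor binding-site enrichment
    factors, and cross-algorithm miRNA-target aggregation with empirical
    permutation enrichment p-values. A synthetic-data generator with planted
    ground truth provides every input the cascade consumes, so each stage has
    a known acceptance surface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    graphics,
    utils,
    jsonlite,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
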