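Package: stromalsig
Title: Stromal Gene-Expression Signatures: Derivation, Projection and
    Outcome Association
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Derives tumor-type-specific gene signatures from multi-group
    3'-end tag-sequencing (3SEQ) expression profiles by two-class
    Significance Analysis of Microarrays (SAM) with permutation-based FDR
    control, projects the signatures onto independent expression cohorts
    with a Cluster 3.0-style hierarchical clustering recipe (Spearman rank
    correlation, centroid linkage), calls signature-positive cases by the
    volume-of-expression rule, derives cross-cohort core gene sets by
    correlation-threshold consensus, and tests outcome association with
    Kaplan-Meier, log-rank and Cox proportional-hazards statistics.
    Includes gene-level quantification and QC for 3SEQ libraries and a
    synthetic-data generator with planted structure so the entire pipeline
    is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    survival,
    SummarizedExperiment,
    S4Vectors,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
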