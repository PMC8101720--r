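Package: comorbsim
Title: Disease Comorbidity Proximity from Transcriptomic Signatures
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Quantifies how strongly the transcriptomic signatures of two
    diseases resemble each other. Implements two-group differential
    expression with an empirical-Bayes moderated t-statistic, Fisher's
    exact over-representation analysis against Gene Ontology terms and
    pathway gene sets, and Wang-style ontology semantic similarity with
    best-match-average lifting to gene sets and disease term sets. A
    pipeline orchestrates per-dataset screening, enrichment, three-level
    similarity matrices (differentially expressed genes, enriched GO
    terms, Disease Ontology terms), overlap reporting and average-linkage
    dendrograms. Self-contained synthetic-data generators (toy ontologies,
    annotation maps, planted-effect expression matrices) support testing
    without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    igraph,
    ape,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    limma,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
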