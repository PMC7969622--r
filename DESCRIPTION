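Package: aopminer
Title: Literature Co-Occurrence Mining and Validation of Adverse Outcome
    Pathway Genesets
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools to engineer adverse outcome pathway (AOP) key-event
    genesets from a literature abstract corpus. Abstracts are mined with a
    dictionary of HGNC gene symbols to form a gene-by-document term-document
    matrix; gene pairs are scored by the cosine similarity of their binary
    document-incidence vectors, ranked with per-abstract evidence, filtered
    by journal impact factor, and curated via a machine-readable decision
    ledger into genesets with seed (S), relevant (R) and additional (A)
    provenance categories. Thresholded co-occurrence networks are exported
    to standard graph formats, and genesets are validated against expression
    matrices by Ward hierarchical clustering, adjusted Rand agreement, and
    principal component analysis with component-covariate association tests.
    A synthetic-data module generates corpora with planted co-mention blocks
    and expression matrices with planted group effects and technical
    confounders so that every stage is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    igraph,
    jsonlite,
    ape,
    S4Vectors,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
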