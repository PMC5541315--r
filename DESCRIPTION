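Package: endonet
Title: Endogenous Molecular Network Dynamics, Gene-Age Enrichment and
    Age-Filtered Prognostic Signatures
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates cancer endogenous molecular networks as continuous
    Hill-function dynamical systems, enumerates and classifies their
    attractors as cell statuses, scores simulation accuracy against
    expression-change annotations, tests gene-age enrichment of cancer
    driver genes with hypergeometric tests and false discovery rate
    correction, and builds gene-age-filtered prognostic signatures with a
    sum-of-expression risk score evaluated by log-rank tests and hazard
    ratios. Includes synthetic-data generators so every stage is testable
    without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    survival
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
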