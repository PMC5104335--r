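Package: cardiodev
Title: Time-Series Transcriptome Analysis of Postnatal Heart Development
Version: 0.1.0
Authors@R:
    person("Artifact", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A reusable pipeline for time-series expression analysis of the
    maturing postnatal heart: background and probe-quality filtering with
    probe-to-gene collapse, quantile normalization, selection of dynamically
    regulated genes by coefficient of variation, hexagonal self-organizing map
    clustering of temporal profiles with PCA visualization and developmental
    stage categorization, weighted co-expression networks (soft thresholding,
    topological overlap) with bootstrap-stabilized hub-gene ranking, moderated-t
    differential expression between knockout and control genotypes with BH FDR
    and fold-change calling, DE-hub intersection, hypergeometric gene-set
    overrepresentation, and PWM-based promoter motif enrichment. Includes a
    synthetic-data generator with known ground truth so every stage is testable
    without microarray downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    limma,
    jsonlite,
    withr
Config/testthat/edition: 3
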