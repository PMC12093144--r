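Package: circscaffold
Title: Structural and Genomic Analysis of Inverted-Alu-Mediated Backsplicing
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for analysing the determinants of circular RNA
    backsplicing mediated by inverted-repeat Alu elements. Provides
    strand-aware classification of exons by flanking-Alu pattern with
    log-odds circularization enrichment and bootstrap uncertainty,
    chemical-probing (SHAPE/DMS) reactivity normalization and regional
    summaries, SHAPE-JuMP crosslink deletion-frequency quantification
    with coordinate lift-over to a reference construct, RNA
    secondary-structure region metrics from CT/dot-bracket/pairing
    probability files, qPCR circularization-efficiency estimation with
    propagated error, and seeded synthetic-data generators that plant
    known ground truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    GenomicRanges,
    IRanges,
    S4Vectors,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    ggplot2,
    jsonlite
Config/testthat/edition: 3
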