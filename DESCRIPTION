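Package: circtype
Title: Cell-Type Specificity and Validation Analysis of Circular RNAs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Downstream analysis of back-splice junction (BSJ) calls from
    laser-capture RNA-seq of brain cell types: expression and RNase-R
    validation filtering of circRNA candidates, Jensen-Shannon cell-type
    specificity scoring and classification, locus architecture (exclusive
    versus super-host circRNA producers), circular-to-linear ratios,
    genomic feature characterization against gene models and interval
    tracks, Fisher's exact gene-set and disease enrichment of host genes,
    and gene-aggregated negative-binomial differential expression with a
    Wald test. A seeded synthetic-data generator reproduces the statistical
    structure the analysis assumes, so every stage is testable without
    access to protected human data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    MASS,
    IRanges,
    GenomicRanges,
    rtracklayer,
    withr,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    DESeq2,
    jsonlite
Config/testthat/edition: 3
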