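Package: praf1
Title: Progesterone Receptor AF1 Activity from Factorial RNA-Seq and ChIP-Seq
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies activation-function-1 (AF1)-dependent progesterone
    receptor activity from a four-cell-line by four-treatment factorial design.
    Provides a self-contained negative-binomial Wald engine for differential
    expression (median-of-ratios normalization, method-of-moments dispersion
    with trend shrinkage, Benjamini-Hochberg adjustment), a mutant-versus-
    wild-type regulation taxonomy (lost, hypo, intermediate, unaffected,
    hyper, opposite, gained), ligand-independent gene calling, estrogen-
    progestin synergy and antagonism classification, and ChIP-Seq consensus
    peaks, TSS binding profiles, differential occupancy and peak-to-expression
    integration. A seeded synthetic-data generator emulates the study design
    (duplicate RNA-Seq, triplicate ChIP-Seq) with known per-gene ground truth
    so that every stage is testable by parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    withr,
    jsonlite,
    yaml,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    S4Vectors
Suggests:
    testthat (>= 3.0.0),
    DESeq2
Config/testthat/edition: 3
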