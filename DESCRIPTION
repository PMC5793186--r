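Package: lncdissect
Title: Dissection of Long Non-Coding RNAs in Time-Course RNA-Seq
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reusable pipeline for identifying and characterizing long
    non-coding RNAs (lncRNAs) from an assembled transcript annotation of a
    staged differentiation time course. Implements a conjunctive filter
    cascade (transcript size, exon count, expression level, overlap with
    known coding and small-RNA loci, and coding-potential score thresholds),
    strand-aware classification into long intergenic (lincRNA) and antisense
    lncRNAs, novelty calling against a known-lncRNA reference, cis-target
    assignment by genomic windows, trans-target assignment by Pearson
    co-expression, stage-wise differential expression with K-means temporal
    archetype clustering, hypergeometric over-representation analysis, and
    qPCR agreement via the 2^-ddCt method. Ships a seeded synthetic-data
    generator with planted ground truth so the whole pipeline is testable
    without sequencing data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    GenomicRanges,
    GenomeInfoDb,
    IRanges,
    S4Vectors,
    Biostrings,
    stats,
    utils,
    methods
Suggests:
    testthat (>= 3.0.0),
    rtracklayer,
    mclust
Config/testthat/edition: 3
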