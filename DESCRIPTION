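Package: paralogdose
Title: Paralog Dose Analysis for Duplicated Transcription Factors
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies the relative contribution of two paralogous
    transcription factor genes (modeled on Stat5a and Stat5b in mouse
    CD4+ T cells) to a shared transcriptional program. Implements RPKM
    offset normalization and low-expression filtering, a small-sample
    differential expression test, a log2 paralog-preference score with
    its 12-bin histogram, a paralog-specificity classifier, relative
    paralog abundance estimation from mRNA levels and from flow
    cytometry MFI across allele-dosage genotypes, and integration of
    per-genotype ChIP-seq peak sets with expression (TSS annotation,
    cross-genotype occupancy hierarchy). A seeded synthetic-data
    generator with planted ground truth exercises every stage without
    external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    withr,
    IRanges,
    GenomicRanges,
    S4Vectors
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
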