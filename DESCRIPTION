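Package: screenaudit
Title: Auditing Multi-Target and Mismatch-Tolerance Biases in Pooled CRISPR Screens
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Tools to detect and quantify biases in genome-wide pooled
    CRISPR knockout screens that arise from guides targeting multiple
    genomic loci and from mismatch-tolerant off-target cutting.
    Provides mismatch-tolerant spacer-to-genome alignment with
    canonical NGG PAM filtering and exon annotation, log-fold-change
    normalization and copy-number correction, cell-line-specific
    cleavage-toxicity curve fitting and adjustment, ordinary
    least-squares interaction statistics (delta coefficient, digenic
    additivity test, guide-design system solver), SNP-in-protospacer
    effect classification with permutation-based genotype-phenotype
    association, and a synthetic screen simulator with planted ground
    truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    BiocGenerics,
    methods,
    stats,
    utils,
    splines
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    rtracklayer,
    GenomicRanges
Config/testthat/edition: 3
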