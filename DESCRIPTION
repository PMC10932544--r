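Package: splicedrift
Title: Alternative-Splicing Rate Quantification and Drift-Barrier Modeling
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies alternative-splicing (AS) rates from spliced RNA-seq
    alignments: splice-junction extraction with anchor, mismatch and splice-signal
    filters; per-intron spliced/alternative/unspliced read counts and the derived
    splicing ratios; classification into major- and minor-isoform introns; minor
    intron relative abundance (MIRA) and per-gene AS rates. Companion analyses
    cover reading-frame preservation of splice variants, expression dependence of
    splicing-error rates, SNP density at splice-site dinucleotides with matched
    control dinucleotides, a gamma/normal mixture model of splicing-error and
    functional-variant rates under the drift-barrier hypothesis, and phylogenetic
    generalized least squares for cross-species comparisons. A synthetic-data
    module generates genomes, annotations, spliced alignments, SNP tables and
    trait-bearing phylogenies so that every stage can be exercised end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    methods,
    Biostrings,
    IRanges,
    S4Vectors,
    GenomicAlignments,
    Rsamtools,
    rtracklayer,
    GenomicRanges,
    ape,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    nlme,
    withr,
    jsonlite
Config/testthat/edition: 3
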