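Package: junctionqtl
Title: Splicing QTL Mapping from RNA-seq Junction Reads
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Derives junction-level splicing phenotypes from aligned RNA-seq
    reads (splicing-efficiency ratios, intron-read percentages, and
    percent-spliced-in for alternative 5' donor events), associates them with
    genotype dosages under a covariate-adjusted linear model with optional
    conditional scans and a single-variance-component REML extension, scans
    exon sequence for allele-specific disruption of exonic splice enhancer
    hexamers, and quantifies mini-gene qPCR splicing ratios by the
    standard-curve method. Ships a synthetic-data generator that emulates a
    cohort of dairy cattle segregating a dinucleotide substitution with
    genotype-dependent splicing efficiency, alternative donor usage and
    expression, together with truth tables for parameter-recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicAlignments,
    GenomicRanges,
    IRanges,
    Rsamtools,
    S4Vectors,
    jsonlite,
    methods,
    rtracklayer,
    stats,
    utils,
    vcfR,
    yaml
Suggests:
    DESeq2,
    lme4,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
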