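Package: embryoTE
Title: Repeat-Aware Retrotransposon Quantification and Single-Embryo
    RNA-Seq Analysis
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for the transcriptomic analysis of mouse preimplantation
    embryos and extraembryonic tissues carrying hypomorphic alleles of an
    X-linked glycosyltransferase: repeat-aware quantification of
    retrotransposon expression from multi-mapper-randomized alignments
    (fragment containment filtering, repName/repFamily FPKM, DNA-transposon
    contamination covariates), in-silico sexing, genotyping and quality
    control of single-embryo RNA-seq libraries (including detection of a
    3-bp deletion allele from soft-clipped reads), a self-contained
    negative-binomial Wald differential-expression engine with
    unwanted-variation factors and independent filtering, signed-rank gene
    set enrichment and developmental-delay statistics, and a seeded
    synthetic-data generator that emulates the full data structure so every
    stage is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    BiocGenerics,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomicAlignments,
    Rsamtools,
    rtracklayer,
    Biostrings,
    SummarizedExperiment,
    MASS,
    matrixStats,
    yaml,
    jsonlite,
    withr
Suggests:
    testthat (>= 3.0.0),
    DESeq2,
    fgsea,
    optparse
Config/testthat/edition: 3
biocViews: Transcriptomics, DifferentialExpression, Sequencing, QualityControl
RoxygenNote: 7.3.3
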