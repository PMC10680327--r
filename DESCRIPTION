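Package: m3Escan
Title: H3K4me3-Enriched Enhancers and Recurrent Variant Enhancer Loci from
    Paired ChIP-Seq Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Identifies TSS-distal active enhancers from H3K27ac ChIP-seq
    peaks, classifies the subset carrying H3K4me3 (m3Es), stitches super
    enhancers, quantifies per-locus RPKM signal, and calls recurrent variant
    enhancer loci (VELs, Vm3Es, VSELs) across cohorts of paired native and
    tumor tissue samples using per-pair fold-change calls, cohort-wide
    merging, and an exact binomial recurrence test with Benjamini-Hochberg
    correction. Ships a synthetic paired-cohort generator with planted
    ground truth (negative-binomial fragment counts, configurable effect
    sizes and recurrence) so every stage of the pipeline is testable at
    desk scale, plus downstream summaries: enhancer-class fractions,
    genomic distribution, target-gene assignment, expression comparison,
    PCA sample classification, and transcription-factor overlap trends.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    SummarizedExperiment,
    rtracklayer,
    withr
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
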