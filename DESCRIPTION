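Package: ReseqScan
Title: Variant Summaries, Relatedness, Presence/Absence and
    Resistance-Gene Analysis for Crop Resequencing Panels
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Compares resequenced crop genotypes against a reference
    assembly. Provides quality/depth variant filtering and per-genotype
    SNP/indel rate summaries, fixed-window zygosity density tracks and
    homozygous-fixed-region scans, identity-by-state distances with UPGMA
    dendrograms, read-count based presence/absence variant (PAV) calling
    and categorization, domain-architecture classification of resistance
    gene analogs (RGAs) with chromosomal cluster detection, variant
    effect and impact annotation with deleterious-call aggregation over
    metabolic-pathway gene sets, and a synthetic-data generator that
    emulates a multi-genotype resequencing study with planted ground
    truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    Biostrings,
    rtracklayer,
    SummarizedExperiment,
    VariantAnnotation,
    ape
Suggests:
    testthat (>= 3.0.0),
    phangorn,
    jsonlite,
    knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
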