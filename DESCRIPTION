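Package: translocatr
Title: Breakpoint Mapping and Junction Analysis for Reciprocal Translocations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for localizing and characterizing reciprocal translocation
    breakpoints from targeted paired-end sequencing. Includes a synthetic
    genome and read simulator with ground-truth records, BAC-FISH style
    probe-interval localization, a k-mer seed-and-extend paired-end mapper,
    inter-chromosomal discordant read-pair clustering, junction consensus
    assembly with microhomology / insertion (NHEJ signature) classification,
    VCF breakend output, in-silico junction PCR genotyping, and comparative-Ct
    relative expression quantification.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    Biostrings,
    BiocGenerics,
    GenomeInfoDb,
    GenomicRanges,
    IRanges,
    jsonlite,
    withr,
    Rsamtools,
    rtracklayer
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    VariantAnnotation
Config/testthat/edition: 3
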