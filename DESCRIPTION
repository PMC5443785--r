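Package: ssrpop
Title: Population-Scale Analysis of Simple Sequence Repeat Variation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Genome-wide cataloguing and population-scale analysis of
    simple sequence repeats (SSRs, microsatellites). Detects perfect
    tandem repeats with 2-6 bp units in genome sequences, normalises
    repeat units to canonical motif classes under cyclic rotation and
    reverse complementation, classifies loci into genomic regions
    (CDS, UTRs, introns, promoters, intergenic), profiles SSR
    enrichment around SINE retrotransposon boundaries, computes
    per-locus population statistics (allele frequencies, minor allele
    frequency, heterozygosity, polymorphism information content) from
    diploid STR genotype tables, filters high-quality polymorphic
    loci, categorises cross-species flank conservation, flags
    potential loss-of-function alleles (frameshift and splice-site),
    and builds neighbour-joining trees from genotype-sharing
    distances. A synthetic-data generator with planted ground truth
    makes the whole pipeline testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    BiocGenerics,
    Biostrings,
    methods,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    ape,
    data.table,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr,
    knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
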