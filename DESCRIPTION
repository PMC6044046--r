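Package: invcall
Title: Detection and Genotyping of Genomic Inversions from Long-Read Split Alignments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Detects genomic inversions from the split (supplementary)
    alignments that long sequencing reads produce across inversion
    breakpoints, classifies them as inverted-repeat (NAHR) mediated or
    blunt (NHEJ-like) events, genotypes each call with a binomial
    posterior model on inversion- and reference-supporting read counts,
    and writes symbolic-allele VCF. Includes a hermetic diploid genome
    and nanopore-style read simulator with an idealized split aligner,
    a reciprocal-overlap benchmarking harness, and tools relating
    inverted-repeat length to the size of the inversion it can mediate
    (log-log regression with prediction-interval filtering).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.2)
Imports:
    Biostrings,
    GenomicAlignments,
    GenomicRanges,
    IRanges,
    S4Vectors,
    Rsamtools,
    data.table,
    jsonlite,
    stats,
    utils
Suggests:
    VariantAnnotation,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
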