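Package: segannot
Title: Segment-Tree Annotation of Genomic Coordinates, Intervals and Variants
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Annotates large sets of genomic coordinates, intervals, single
    nucleotide variants, indels and translocations against transcript models
    (genePred, BED or PSL) using a binned segment-tree index instead of a
    database server. Classifies hits into exon/intron/UTR/CDS/splice-site and
    upstream/downstream categories, calls synonymous, non-synonymous and
    nonsense changes with full mutated protein sequences, looks up known SNPs,
    finds closest transcription start sites with distance histograms, and
    emits per-category tallies. Includes a deterministic synthetic-fixture
    generator and naive reference oracles for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    Biostrings,
    data.table,
    stats,
    tools,
    utils,
    vcfR
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    GenomicRanges,
    IRanges,
    S4Vectors,
    seqinr,
    rtracklayer,
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
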