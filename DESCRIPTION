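Package: palmkaryo
Title: Synteny Blocks, Ancestral Karyotypes, Molecular Dating and
    Multi-Omics Networks for Palm Genomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Comparative-genomics and multi-omics toolkit built around
    haplotype-resolved palm genomes. Detects collinear synteny blocks
    between gene orders by anchor chaining, reconstructs ancestral
    chromosome groups and paints extant chromosomes, accounts for
    whole-genome duplication, fusion and fission events, estimates
    synonymous-site divergence (Nei-Gojobori with Jukes-Cantor
    correction) and dates duplications with a molecular clock, ages LTR
    retrotransposon insertions from Kimura two-parameter divergence,
    calls allele-specific expression from allelic gene pairs, screens
    differentially accumulated metabolites with PLS-DA VIP scores, and
    builds signed gene-metabolite correlation networks. Ships a genome
    and omics simulator with known ground truth so every stage is
    testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    Rcpp,
    S4Vectors,
    igraph,
    jsonlite,
    rtracklayer,
    stats,
    utils,
    withr
LinkingTo:
    Rcpp
Suggests:
    ape,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
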