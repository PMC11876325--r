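Package: ratecov
Title: Evolutionary Rate Covariation and Genomic Overlap Permutation Tests
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes relative evolutionary rates (RER) from per-gene
    phylogenetic branch lengths, the evolutionary rate covariation (ERC)
    statistic between gene pairs (Winsorized Pearson correlation, Fisher
    z-transformed and scaled by shared branch count), and permutation tests
    comparing protein-complex ERC against random gene sets. Also provides
    genomic interval overlap statistics with a random-genome permutation
    null for ChIP-seq peak/feature enrichment, and synthetic-data
    generators with planted rate covariation and planted peak enrichment
    for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    ape,
    GenomicRanges,
    IRanges,
    S4Vectors,
    GenomeInfoDb,
    rtracklayer,
    jsonlite,
    stats,
    utils,
    tools,
    methods
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
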