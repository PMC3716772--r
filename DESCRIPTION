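Package: panforge
Title: Bacterial Pan-Genome Analysis with Gene-Trait Matching
Version: 0.9.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: A desk-scale comparative pan-genomics pipeline for bacterial
    draft genomes. Builds consensus gene calls from multiple predictor
    tracks by majority vote, infers ortholog groups with a reciprocal-best-hit
    graph and Markov clustering, derives gene presence/absence matrices with
    pan/core accumulation curves, orders draft contigs against a finished
    reference (pseudo-assembly) with GC profiling, classifies putative
    plasmid contigs, detects CRISPR repeat/spacer arrays and strain CRISPR
    types, builds core-gene and gene-content strain trees, and matches gene
    presence to binary growth phenotypes with Random-Forest feature
    importance. Ships a synthetic strain-panel generator with full ground
    truth so that every stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    rtracklayer,
    Matrix,
    igraph,
    ape,
    randomForest,
    jsonlite,
    yaml,
    stats,
    utils,
    tools,
    methods
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
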