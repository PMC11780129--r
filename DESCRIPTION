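Package: phagenick
Title: Detection and Comparative Analysis of Single-Strand Nicks in Phage
    Genomes from Strand-Specific Long-Read Coverage
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Detects single-stranded DNA breaks (nicks) in bacteriophage
    genomes by comparing strand-specific long-read sequencing depth of
    native DNA against a whole-genome-amplified (WGA) control, recovers
    the shared degenerate (IUPAC) motif at nick sites, and characterises
    the motif's conservation across a genome collection: per-strand
    occurrence counts with an analytic chance expectation, weighted gene
    repertoire relatedness (wGRR) from bidirectional best protein hits
    with hierarchical clustering, and positional statistics on
    terminase-reoriented genome coordinates and relative to coding
    sequences. Includes a fully parameterised synthetic-data generator
    (nicked genomes, strand-truncated read sets, matched controls,
    annotated multi-genome families) with recorded ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    IRanges,
    S4Vectors,
    GenomicRanges,
    Rsamtools,
    rtracklayer,
    jsonlite,
    stats,
    utils,
    methods
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
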