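Package: mitorecomb
Title: Repeat-Mediated Recombination and RNA Editing in Plant
    Mitochondrial Genomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for characterizing the structural dynamics of circular
    plant mitochondrial genomes from sequencing data.  The package finds
    dispersed repeat pairs (direct and inverted) with a bounded number of
    mismatches on a circular genome, builds master and alternative junction
    references for each repeat pair, classifies junction-spanning long
    reads to quantify repeat-mediated recombination frequencies, and calls
    C-to-U (and rarer) RNA-editing sites in mitochondrial protein-coding
    transcripts from read pileups, including start-codon creation events.
    A synthetic-data module generates circular genomes, conformational
    read mixtures and edited RNA-seq reads with known truth so that every
    stage of the pipeline can be validated by simulation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    Rsamtools,
    rtracklayer
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
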