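Package: afptools
Title: Analysis of Tandem Antifreeze-Protein Gene Arrays and Their Gig2 Provenance
Version: 0.9.0
Authors@R:
    person("AFP", "Tools Developers", email = "afptools@example.org",
           role = c("aut", "cre"))
Description: A reusable pipeline for characterizing multigene antifreeze
    protein (AFP) loci of the kind found in righteye flounders: estimation of
    tandem-repeat copy number from long-read category counts with bootstrap
    uncertainty, seed-and-extend local homology mapping contrasting coding
    and non-coding similarity, AFP isoform classification
    (skin/liver/Midi/Maxi/pseudogene/Gig2-like) from gene models,
    microsynteny comparison across species to detect gene-family relocation,
    and virtual Southern-blot band prediction.  A synthetic-locus generator
    (circular BAC molecules with near-identical tandem units, error-bearing
    long reads, allele pairs, provenance pairs and synteny scenarios) makes
    every stage testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    data.table,
    Rcpp,
    stats,
    utils,
    tools,
    methods
LinkingTo: Rcpp
Suggests:
    withr,
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
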