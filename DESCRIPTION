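Package: NGDprofiler
Title: Size-Resolved Ribosome Footprint Analysis of No-Go mRNA Decay
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing ribosome-profiling evidence of No-Go Decay
    (NGD): construction of stall-reporter transcript models, simulation of
    footprint libraries with realistic adapter/UMI structure, adapter and
    UMI trimming, ungapped transcriptome placement with untemplated-A
    detection, size-class A-site and cleavage-point inference with offset
    calibration from start codons, occupancy tracks, peak calling and
    collided-ribosome spacing statistics, premature-polyadenylation and
    endonuclease-target detection from short footprints, and scoring of
    dual-reporter fluorescence colony-array screens (filtering, LOESS
    spatial normalization, Z-scores, hit calling).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    graphics,
    grDevices,
    Rcpp,
    Biostrings,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    S4Vectors,
    GenomicAlignments,
    Rsamtools,
    rtracklayer,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    DESeq2,
    optparse
Config/testthat/edition: 3
biocViews: Transcriptomics, RiboSeq, Sequencing, Software
RoxygenNote: 7.3.3
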