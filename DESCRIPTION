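Package: ncyc
Title: Nitrogen-Cycle Marker Gene Profiling for Shotgun Metagenomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end pipeline for inventorying nitrogen-cycle marker
    genes (narG, napA, nxrA, nirK, nirS, nor, nod, nosZ, nrfA, hao, hzsA,
    amoA, nifH) in shotgun metagenomes from stratified sediments. Implements
    length-based read QC, small-subunit rRNA fragment recruitment against a
    reference set with lineage assignment, six-frame translated
    Smith-Waterman search of reads against curated functional-gene protein
    databases with Karlin-Altschul bit scores and E-values, two-database
    bit-score-ratio curation of false-positive homology hits, MEGAN-style
    lowest-common-ancestor taxonomic binning, and cross-sample normalized
    read-count (nrc) quantification. Ships a synthetic sediment-community
    read simulator with ground truth so every stage is testable without
    external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    dplyr,
    Rcpp,
    stats,
    tibble,
    utils,
    withr
LinkingTo: Rcpp
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
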