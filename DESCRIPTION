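Package: olekit
Title: Detection, Network Analysis and Product Modelling of Bacterial
    Olefin Biosynthesis (oleABCD) Gene Clusters
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for surveying olefin biosynthesis in bacterial genomes
    and for modelling the olefin products of the ole pathway. Implements a
    compact PROSITE-style motif scanner for finding putative OleA thiolases,
    a Smith-Waterman local aligner with Karlin-Altschul E-values for
    verifying oleBCD homologs in the gene neighborhood (+/- 5000 bp),
    sequence-similarity-network construction with identity-based node
    collapsing, mapping of cluster presence onto species phylogenies with
    genus-level ubiquity statistics, internal-standard quantification of
    GC/MS olefin and fatty-acid peak tables, and a generative head-to-head
    condensation model linking fatty-acyl precursor pools and OleA substrate
    specificity to olefin chain-length and branch-isomer distributions,
    including maximum-likelihood specificity fitting and in-silico oleA swap
    experiments. Seeded synthetic-data generators produce every input the
    pipeline consumes together with machine-readable ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    Biostrings,
    ape,
    igraph,
    jsonlite,
    rtracklayer,
    GenomicRanges,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
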