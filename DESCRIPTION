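Package: mgescout
Title: Mobilome Characterization in Assembled Bacterial Genomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Detects and characterizes candidate mobile genetic elements
    (plasmids and integrative conjugative elements) in assembled bacterial
    genomes, with an emphasis on the mycobacterial mobilome. Provides a
    maximal direct/inverted repeat finder (terminal inverted repeats,
    circularity overlaps, direct-repeat element boundaries), replicon
    topology inference from terminal redundancy and spanning read pairs,
    ESX (type VII secretion system) locus calling and signature-based
    typing from domain-tagged annotations, a feature-matrix element
    classifier (conjugative plasmid, cryptic plasmid, putative ICE), a
    k-mer anchor-and-chain shared-segment comparator, and a synthetic
    replicon generator that plants all of these architectures with known
    ground truth so the whole pipeline is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    BiocGenerics,
    Biostrings,
    GenomeInfoDb,
    Rcpp,
    rtracklayer,
    S4Vectors,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
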