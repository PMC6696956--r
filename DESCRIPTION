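Package: prophagekit
Title: Prophage Induction, Excision and Comparative Genomics Toolkit
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for studying temperate phages of fast-growing Vibrio
    hosts: detection of induced prophages from supernatant-sequencing
    coverage, a site-specific recombination model for attL/attR/attB/attP
    attachment sites (direct-repeat core discovery, crossover inference,
    in-silico excision and integration), absolute qPCR quantification of
    spontaneous prophage induction and strain ratios via standard curves,
    serial-passage competition modelling with selection-coefficient
    estimation, and MinHash sketch distances with fragment-based average
    nucleotide identity for phage genome comparison. A synthetic-data
    generator emulates host chromosomes with implanted prophages,
    supernatant coverage tracks, qPCR plates and competition read-outs so
    the whole pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
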