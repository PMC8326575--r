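Package: amfpipe
Title: Amplicon Community Analysis of Arbuscular Mycorrhizal Fungi
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: A reusable pipeline for LSU rDNA amplicon surveys of arbuscular
    mycorrhizal fungal (AMF) communities: demultiplexing and quality
    filtering of pyrosequencing-style reads, assignment of reads to known
    reference taxa under a dual coverage/identity criterion, greedy de novo
    clustering of unassigned reads under the same criterion, abundance
    normalization by rarefaction, presence and median filtering, alpha and
    beta diversity statistics (rarefaction curves, Shannon/Simpson indices,
    Bray-Curtis distances, principal coordinate analysis, PERMANOVA),
    heat-tree style and LEfSe-style differential abundance analysis, and
    Trouvelot scoring of mycorrhizal root colonization. A seeded synthetic
    data module generates mock reference databases and error-bearing reads
    with full ground truth so every stage is testable without external data.
License: MIT
Encoding: UTF-8
Imports:
    Biostrings,
    MASS,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    vegan,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
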