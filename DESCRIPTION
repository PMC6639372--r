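Package: dtpnet
Title: Network-Based Drug Target Prioritization with One-Class Support
    Vector Machines
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Prioritizes candidate drug target genes in a disease context
    (hepatocellular carcinoma in the motivating application) by combining
    protein-protein interaction network topology with genetic dependency
    (CRISPR essentiality) screens. For every gene in an interaction
    network the package derives centralities, shortest-path proximities
    to six disease-related gene classes, neighbor class composition, and
    per-cell-line dependency scores of the gene and its neighbors; trains
    a one-class support vector machine on known drug targets only; and
    evaluates it with repeated five-fold cross-validation, consensus
    calling, sensitivity/specificity/MCC/AUC, Fisher enrichment, and
    Wilcoxon group-comparison batteries. A seeded synthetic-data
    generator emulates the observed network and essentiality structure
    so the whole pipeline is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    e1071,
    igraph,
    jsonlite,
    Matrix,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
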