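Package: paraclust
Title: Detection of Chromosomal Clusters of Paralogous Genes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Identifies paraclusters, groups of ancestrally related
    (paralogous or domain-sharing) genes lying closer together along a
    chromosome than expected by chance. Genes are placed in rank order
    along chromosomes, candidate clusters are built by a greedy
    annotation-chaining scan with gap rules and nested-array gap
    collapsing, scored with the hypergeometric tail probability and a
    genome-wide expectation correction, filtered at an expectation
    threshold, and merged across multiple annotation datasets. Also
    provides chromosome-walk proximity profiles with permuted-genome
    baselines, genome summary metrics, cross-species cluster sharing via
    ortholog maps, and a seeded synthetic-genome generator with a
    ground-truth ledger for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    withr,
    yaml
LinkingTo:
    Rcpp
Suggests:
    optparse,
    rtracklayer,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
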