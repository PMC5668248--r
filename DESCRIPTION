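Package: mirframe
Title: miRNA Discovery, Target Scoring and Differential Network Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A six-stage analysis pipeline for comparing miRNA regulation
    between two transcriptome conditions (for example healthy versus
    virus-infected plant tissue): homology-based miRNA precursor discovery
    with hairpin-structure validation under a built-in nearest-neighbour
    folding model, psRNATarget-style miRNA/mRNA duplex expectation scoring
    with inhibition-mode calls, bipartite miRNA-target network construction
    with degree and degree-correlation profiling, a decay-weighted Gene
    Ontology node-score network over a user-supplied DAG, and weighted
    co-expression network reconstruction from abundance, GO-overlap and
    Pearson-correlation components. Includes a fully seeded synthetic-data
    generator (planted precursors, target sites, GO DAGs and replicate FPKM
    tables) so every stage can be exercised and validated without external
    downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
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
    stringr,
    tibble,
    tidyr,
    tools,
    utils,
    withr
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
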