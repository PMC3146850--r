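Package: chapnet
Title: Distribution of Chaperonin Substrate Enzymes in Metabolic Reaction Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds Escherichia coli metabolic reaction networks from KEGG
    KGML pathway files (nodes are enzyme-catalysed reactions, edges are shared
    essential substrate-product metabolites), reduces them to the undirected
    largest connected component, and analyses how chaperonin (GroEL/GroES)
    substrate enzymes are distributed on the network: class-stratified
    shortest-path profiles from a central node (pyruvate kinase by default),
    within-class pairwise distance profiles, traditional per-node measures
    (degree, closeness, betweenness, clustering coefficient), nonparametric
    class comparisons (Kruskal-Wallis, Wilcoxon rank-sum, Student's t), and an
    ortholog-based conservation score. A synthetic-data generator emulates all
    pipeline inputs (an expanding network, age-biased class labels,
    class-dependent ortholog retention, position-independent abundance) so the
    whole pipeline is testable without database downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    xml2
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
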