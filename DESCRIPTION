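Package: herbwalk
Title: Biased Random-Walk Prioritization of Herbs and Compounds on a
    Multiscale Interactome
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds a multilayer network joining protein-protein
    interactions, protein-to-biological-function annotations, and a
    function hierarchy, and propagates influence over it with a
    class-biased random walk with restart.  Diffusion profiles seeded at
    herb, compound, or disease nodes are compared by correlation to
    prioritize herbs and their constituent compounds against a disease,
    with one-sided hypergeometric overlap tests and fold-enrichment
    statistics, gene-set over-representation analysis of target lists,
    and extraction of top-k mechanism subnetworks connecting a compound
    to disease-relevant proteins and functions.  A synthetic-world
    generator with a planted disease-proximal herb supports end-to-end
    testing without any external database.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    Matrix,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
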