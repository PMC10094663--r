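Package: ucattractor
Title: Phylostratum-Resolved Interactome Analysis of the Unicellular Attractor
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for detecting a unicellular attractor in cellular networks:
    phylostratum-resolved centrality profiling of confidence-filtered
    protein-interaction networks, random-walk endpoint simulation with
    gene-number normalization, quantile-normalized expression fold profiles
    across evolutionary strata with analysis-of-means decision limits, and a
    Monte-Carlo mean-contrast enrichment test over a Gene Ontology style DAG
    with annotation propagation and false-discovery-rate correction. Includes
    seed-deterministic generators for age-layered core-periphery networks,
    stratified expression matrices with planted fold gradients, and annotated
    DAGs, so the whole analysis is reproducible without external downloads.
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
    yaml
LinkingTo: Rcpp
Suggests:
    limma,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
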