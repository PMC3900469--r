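Package: igapso
Title: Gene Regulatory Network Inference with an Island-Model Hybrid
    GA-PSO over Decoupled S-Systems
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Infers S-system models of gene regulatory networks from
    time-series expression data by fitting each gene's decoupled power-law
    rate equation with a hybrid genetic-algorithm / particle-swarm
    optimizer. Supports coarse-grained island-model parallelism on a
    binary hypercube topology with synchronized migration, a map/reduce
    style execution backend on a local worker pool, a GeneNetWeaver-style
    synthetic benchmark generator, try-until-success expected-cost
    estimation from Beta posteriors, and Amdahl speed-up accounting.
    Results are returned as tibbles with broom-style tidiers and ggplot2
    visualisations.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    parallel,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
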