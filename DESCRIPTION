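Package: ecoassembly
Title: Null-Model Quantification of Microbial Community Assembly Processes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Quantifies the relative contributions of deterministic and
    stochastic assembly processes to microbial community composition using
    phylogenetic (beta nearest-taxon index, bNTI) and taxonomic (Raup-Crick
    on Bray-Curtis, RC-bray) null models, following the two-step
    classification of community pairs into heterogeneous selection,
    homogeneous selection, dispersal limitation, homogenizing dispersal and
    drift. Includes Bayesian microbial source tracking by collapsed Gibbs
    sampling, core-taxon detection, Spearman co-occurrence networks,
    hierarchical clustering of assembly profiles, correlation of assembly
    determinism with community-internal factors, and a synthetic-community
    generator with known assembly regimes for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    ape,
    vegan,
    picante,
    dplyr,
    tidyr,
    tibble,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    yaml,
    withr,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
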