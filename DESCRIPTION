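Package: exodel
Title: Exome Read-Depth Deletion Discovery and Case-Control Interpretation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Discovery and interpretation of rare genic deletions from exome
    read depth in case-control cohorts. Implements PCA-based depth
    normalization with a three-state hidden Markov model for deletion
    calling and phred-scaled segment qualities, deletion filtering against
    in-house controls and reference CNV frequency maps, large/rare-deletion
    burden testing by phenotype-label permutation, genotype and site quality
    control with a composite deleterious-variant classifier, a
    compound-heterozygote screen extended to first-order protein-interaction
    partners on a brain-specific network, and hypergeometric gene-set
    over-representation against a brain-expressed background. A seeded
    synthetic-cohort generator provides depth matrices, variant tables,
    interaction networks and reference maps with the statistical structure
    each stage assumes, so the full pipeline runs without external data.
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
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    fgsea,
    jsonlite,
    testthat (>= 3.0.0),
    vcfR,
    withr
Config/testthat/edition: 3
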