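Package: commscape
Title: Inference and Comparison of Intercellular Communication Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Infers cell-cell communication networks from grouped single-cell
    expression matrices and a ligand-receptor interaction database with
    multi-subunit complexes and cofactors. Communication strength between two
    cell groups is scored with a mass-action Hill model on robust (trimean)
    group expression, with agonist/antagonist and co-receptor modulation, and
    significance is assessed by a cell-label permutation test. Downstream
    tools quantify sender/receiver/mediator/influencer roles via weighted
    directed network centrality, discover global communication patterns by
    non-negative matrix factorization with consensus-based rank selection,
    and compare signaling networks across conditions through functional and
    structural similarity, shared-nearest-neighbor smoothing, UMAP manifold
    embedding and consensus k-means grouping. A synthetic-data generator with
    planted communication structure supports end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    igraph,
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    ggplot2,
    readr,
    jsonlite,
    yaml,
    uwot,
    cluster,
    generics,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
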