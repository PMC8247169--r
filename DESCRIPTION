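Package: gnstates
Title: Cell-State Scoring, Spatial Enrichment and Trajectory Analysis for
    Developing Granule Neurons and Medulloblastoma
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for comparing developing cerebellar granule-cell states with
    medulloblastoma cells from single-cell and spatial transcriptomics data:
    bin-matched gene-signature scoring with maximum-score state assignment,
    cell-cycle scoring with MAD-threshold binarization, one-tailed rank-sum
    marker detection, hypergeometric intersection grids between cell-type and
    spatial-region gene sets, Moran's I gene-module discovery over a cell kNN
    graph, steady-state RNA-velocity transition matrices with destination
    quantification and chi-square comparison, per-tumor non-negative matrix
    factorization meta-programs, moving-average copy-number inference, and
    kNN-regression lineage similarity. Includes a ground-truth-labeled
    synthetic-data generator emulating the developmental cerebellum, multi-cell
    spatial spots, and tumors with planted chromosome-scale aberrations.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Matrix,
    dplyr,
    generics,
    ggplot2,
    methods,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    ape,
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
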