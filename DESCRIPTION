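Package: trimcells
Title: Trimmed Cell Clusters and Marker-Gene Robustness for scRNA-Seq
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Identifies extreme ("border") cells within single-cell RNA-seq
    clusters by quantile trimming of per-cluster k-nearest-neighbour minimum
    distances in the high-dimensional normalized expression space, with a
    two-dimensional alpha-hull variant operating on embedding coordinates.
    Quantifies the robustness of per-cluster marker-gene selection by
    comparing full versus trimmed analyses through marker-set overlap
    proportions and breakdown-point retention profiles. Includes a minimal
    standard analysis pipeline (normalization, highly variable gene
    selection, PCA, graph clustering, t-SNE), a Wilcoxon one-vs-rest marker
    detector, and seeded synthetic-data generators for multivariate-normal
    locational-shift scenarios and planted-outlier count data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    FNN,
    generics,
    ggplot2,
    igraph,
    MASS,
    Matrix,
    methods,
    purrr,
    readr,
    rlang,
    Rtsne,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    deldir,
    jsonlite,
    mclust,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
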