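Package: mixedclust
Title: Clustering and Integrative Visualization of Mixed-Type Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for cluster analysis of tables whose variables live on
    different scales (quantitative, ordinal, nominal, binary). Samples are
    compared with Gower's general similarity coefficient, including Podani's
    rank-based ordinal score, per-variable weights and missing-value handling.
    Variables are compared with two dissimilarity constructions: a combination
    of association measures (absolute Spearman correlation, Goodman-Kruskal
    gamma, category reordering with pre-tests, and a nearest
    positive-semidefinite repair so that sqrt(1 - s) distances are Euclidean),
    and a bias-corrected generalized distance correlation built from
    type-specific metrics. Includes Ward hierarchical clustering helpers,
    misclassification and balanced error rates, simulation generators for
    validating the measures, and ggplot2-based integrative heatmaps and
    similarity scatter displays.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    dplyr,
    generics,
    ggplot2,
    MASS,
    Matrix,
    patchwork,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    cluster,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
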