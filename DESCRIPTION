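Package: consensusde
Title: Consensus Differential Expression Across Normalization and Model Grids
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Consensus calling of differentially expressed genes from two-group
    bulk RNA-seq count data. Runs a grid of count normalizations (TMM, TMM-CPM,
    RPKM, upper-quartile, full-quantile, median, PoissonSeq-style depth
    estimation, RUV-style factor removal) crossed with five differential
    expression models (negative-binomial Wald, robust negative-binomial
    likelihood-ratio, voom moderated t, Mann-Whitney, Welch t), adjusts each
    grid cell by Benjamini-Hochberg, aggregates q-values per model by their
    mean across normalizations, and calls a gene differentially expressed when
    every model's mean q-value falls below a threshold (default 0.25). Includes
    a seeded negative-binomial count simulator with planted fold changes,
    library-size heterogeneity and optional hidden factors, plus truth-aware
    evaluation (type-I error, FDR, power, effect recovery), volcano
    classification and DEG-set comparison utilities.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    BiocGenerics,
    dplyr,
    generics,
    GenomicRanges,
    S4Vectors,
    ggplot2,
    jsonlite,
    limma,
    MASS,
    Matrix,
    purrr,
    rlang,
    rtracklayer,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    edgeR,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
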