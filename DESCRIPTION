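Package: coexnet
Title: Gene Co-Expression Network Inference and Topology Analysis for
    Small Tumor Transcriptome Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Builds gene co-expression networks from small gene-by-sample
    expression matrices by thresholding absolute Pearson correlations,
    scans the cutoff range to select the most modular network, and
    characterises the result: degree distribution and power-law fit,
    average-shortest-path diameter, betweenness and clustering
    coefficients, Louvain modularity clustering with hypergeometric
    gene-set enrichment, degree-preserving (Maslov-Sneppen) and G(n,m)
    random-graph null comparisons, attack/error robustness curves, and a
    two-group differential-expression overlay with a CREB-target
    (binding value / binding ratio) filter. Includes a seeded synthetic
    expression generator with planted co-expression modules, hubs and
    group differences so the full pipeline is testable end to end.
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
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    jsonlite,
    mclust,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
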