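Package: superpathr
Title: Consolidation of Redundant Pathway Gene Sets into SuperPaths
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Clusters redundant biological pathways from heterogeneous sources
    into unified gene-set clusters (SuperPaths) using a two-threshold
    gene-content similarity algorithm: single-linkage core edges at an upper
    Jaccard cutoff combined with best-neighbor edges at a lower cutoff, plus
    small-pathway absorption and identical-set handling. Includes threshold
    selection by a uniqueness-plus-informativeness objective with
    dilution-resampling stability, evaluation statistics (novel gene-pair
    enrichment against size-matched random controls, name/content concordance,
    over-representation comparison), a synthetic corpus generator with planted
    module structure, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    optparse,
    rlang,
    stats,
    tibble,
    utils,
    withr
Suggests:
    jsonlite,
    mclust,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
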