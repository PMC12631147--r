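Package: evimap
Title: Evidence Maps, Bibliometric Networks and Altmetrics for Meta-Analytic Evidence Bases
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Converts the qualitative side of a meta-analytic evidence base --
    study characteristics, bibliographic metadata, and alternative impact
    metrics -- into computed summaries and publication-style figures:
    evidence-gap-map grids with pooled effects (multivariate fixed-effect
    pooling under correlated sampling errors, DerSimonian-Laird random
    effects, cluster-robust variance), alluvial moderator flows,
    phylogenetically annotated species forests with Grafen branch lengths and
    Brownian-motion correlation, co-authorship and country
    bibliographic-coupling networks, and altmetric orchard plots. Includes a
    seeded synthetic-data generator so every pipeline is testable offline,
    and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    dplyr,
    ggplot2,
    grDevices,
    graphics,
    igraph,
    jsonlite,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    curl,
    metafor,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
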