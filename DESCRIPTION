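Package: cdremir
Title: Commodore MicroRNA Discovery in miR-Gene Co-Expression Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Reconstructs bipartite microRNA-gene co-expression networks from
    paired expression matrices using a plug-in mutual-information estimator on
    equal-frequency bins, thresholds them at a global upper quantile of all
    candidate links, and classifies "commodore" microRNAs: highly connected
    (degree >= 100), non-redundant (bipartite redundancy coefficient <= 0.5)
    miR nodes that are candidate non-redundant controllers of gene modules.
    Commodore gene neighbourhoods are characterised by hypergeometric
    over-representation against an annotation database and the enriched terms
    are aggregated into function groups by average-linkage clustering of Wang
    semantic similarity over the ontology DAG. Includes a synthetic-data
    generator with planted driver and redundant-hub structure so the whole
    pipeline is testable without external downloads.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    Matrix,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
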