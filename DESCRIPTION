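Package: ipcon
Title: Intron Position Conservation Analysis for Ortholog Clusters
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Maps intron positions from gene structures onto protein
    coordinates, builds bidirectional-best-hit ortholog clusters extended
    with the closest non-orthologs and non-inparalogs, scores intron
    position conservation (IPC) between all pair types through a multiple
    alignment, and runs the downstream comparative statistics
    (rank-sum tests, identity-controlled binning, Spearman correlations,
    bootstrap-split agreement) and hypergeometric term-enrichment
    analyses with term-association networks. A self-contained gene-family
    simulator with known orthology and intron histories provides test
    data for every stage.
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
    jsonlite,
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
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
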