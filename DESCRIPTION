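Package: lipidnet
Title: Glycerolipid Composition Statistics and Co-Expression Regulatory
    Networks for Temperature-Stressed Microalgae
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing glycerolipid remodelling and its
    transcriptional regulation in microalgae under temperature stress.
    Parses lipid shorthand nomenclature (e.g. "TAG 52:3",
    "MGDG36:6(18:3/18:3)") into structured species records; computes
    class totals, mol% composition under several denominator scopes,
    fold changes, the double-bond index (DBI) and fatty-acid composition
    from long-format lipidome tables; performs Kruskal-Wallis group
    comparisons with an optional exact permutation mode; derives per-gene
    log2 fold-change profiles from RT-qPCR Ct data by the 2^-ddCt method;
    and builds thresholded Pearson co-expression networks between
    transcription factors and lipid-metabolism genes, with hub summaries
    and Cytoscape-ready exports (SIF, GraphML). A seeded synthetic-data
    module generates lipidomes and expression time-courses with known
    ground truth for end-to-end validation.
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
    stringr,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    readxl,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
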