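Package: xylevo
Title: Growth and Expression Analysis of Experimental Evolution on Xylulose
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing laboratory-evolution experiments in which
    microbial strains are serially propagated on a novel carbon source such as
    xylulose. Extracts growth parameters (log-phase rate, maximum optical
    density, time to saturation, effective growth rate) from plate-reader
    OD600 time series and computes evolved/ancestor fold changes; normalises
    RNA-seq count matrices to counts per million, forms per-strain
    log2 xylulose/glucose expression ratios, projects them onto named gene
    sets with hypergeometric enrichment, and correlates per-strain expression
    change of a gene group with growth improvement. A seedable synthetic-data
    generator produces logistic growth curves and negative-binomial count
    matrices with growth-rate-coupled module effects so that every pipeline
    stage can be exercised and validated without external data.
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
    grid,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
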