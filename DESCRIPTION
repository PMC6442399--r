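Package: botanitox
Title: Quantitative High-Throughput Screening Pipeline for Botanical Mixtures
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for quantitative high-throughput screening
    (qHTS) of botanical and dietary-supplement substances. Raw 384-well
    plate reads are normalized to percent response against plate controls,
    noise-filtered into concentration-response curves, and summarized into
    four activity parameters (weighted area-under-curve, point-of-departure,
    EC50, Emax). Per-run curves are aggregated into active/inactive/
    inconclusive calls by a replicate-majority rule with counter-screen
    interference handling, and bioactivity profiles are analysed by
    hierarchical clustering, rank correlation, ANOVA enrichment, substance
    ranking, and t-SNE embedding. A plate-level simulator with known
    ground-truth Hill responses supports end-to-end testing without
    external screening data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    readr,
    rlang,
    stats,
    utils,
    yaml,
    Rtsne
Suggests:
    testthat (>= 3.0.0),
    pracma,
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
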