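Package: screentriage
Title: Ultra-High-Throughput Screening Triage and Hit Qualification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: A complete, testable triage pipeline for ultra-high-throughput
    enzyme-inhibition screening campaigns in 1536-well format: plate quality
    control (Z'-factor, signal-to-background, robust Z-scores), threshold and
    rescue rules for staged hit calling, Laplacian-corrected naive Bayes
    enrichment on binary fingerprints, four-parameter logistic dose-response
    fitting with censoring and Cheng-Prusoff competitive-shift analysis,
    zinc-chelator deselection, differential scanning fluorimetry melting-point
    extraction and thermal-shift classification, Michaelis-Menten kinetics from
    progress curves, physicochemical prioritization (molecular masses, adduct
    m/z, Lipinski counts, TPSA, QED, lipophilic efficiency), and an end-to-end
    funnel that produces a capped, diversity-aware qualified hit list. A
    seeded synthetic-campaign generator with latent compound mechanism classes
    (inhibitors, zinc chelators, quenchers, chromophores, aggregators) makes
    every stage testable against ground truth without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    readr,
    generics,
    jsonlite,
    minpack.lm,
    deSolve,
    signal,
    ChemmineOB,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    pracma,
    withr,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
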