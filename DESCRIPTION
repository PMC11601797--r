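Package: htscurate
Title: Hierarchical Curation, Early-Recognition Evaluation and Standard
    Splits for High-Throughput Screening Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for turning raw high-throughput screening (HTS) campaign
    tables into curated active/inactive datasets and for benchmarking
    virtual-screening models on them. Implements a hierarchical curation
    pipeline (duplicate removal, primary/confirmatory/counter screen label
    assignment, parser, inorganic, mixture, neutralization, aromatization,
    PAINS and Rule-of-Five filters) with a per-record audit ledger;
    early-recognition metrics (logAUC over a restricted false-positive-rate
    range, BEDROC, enrichment factor, discounted cumulative gain); adapted
    cross-validation and Bemis-Murcko scaffold splits; 2D/3D molecular graph
    featurization with a documented 28-slot atom feature schema; and a
    synthetic campaign simulator with analytically known curation outcomes
    for end-to-end testing without any database download.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    ChemmineR,
    ChemmineOB,
    igraph,
    jsonlite,
    yaml,
    stats,
    utils,
    methods
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
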