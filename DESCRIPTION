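Package: repromine
Title: Profiling Chemicals for Male Reproductive Developmental Toxicity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A systems-toxicology pipeline for profiling chemicals against
    male reproductive developmental toxicity (MRDT). Transforms animal-study
    endpoint tables (ToxRefDB-style exports) into category-level
    lowest-effect-level (cLEL) matrices, potency effect scores, MRDT flags,
    co-occurrence hierarchies, cross-species and cross-generation concordance
    statistics, and Ward hierarchical clusterings. Scores in vitro
    high-throughput screening data (ToxCastDB-style concentration-response
    series) with Hill and gain-loss curve fits, hit calls, and a
    cytotoxicity-adjusted gene Z-score that separates selective bioactivity
    from the nonspecific cytotoxicity burst. Assembles the two data streams
    into a weighted bipartite chemical-target network with deterministic
    force-directed layout and GraphML/GEXF export. Ships a synthetic-data
    generator with planted ground truth so every stage is testable without
    database access.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    tibble,
    dplyr,
    tidyr,
    readr,
    rlang,
    igraph,
    ape,
    jsonlite,
    xml2
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
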