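Package: netpharm
Title: Network Pharmacology Screening, Network Construction and Enrichment
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A reproducible network-pharmacology workflow for multi-herb
    formulas: ADME-style screening of compound tables by oral bioavailability
    and drug-likeness, cross-herb deduplication, intersection of predicted
    compound targets with disease-gene lists, construction of
    herb-compound-gene tripartite networks with degree-based key-compound
    selection, filtering of scored protein-protein interaction edge tables
    into hub statistics, hypergeometric (one-sided Fisher) pathway
    enrichment with Benjamini-Hochberg adjustment, and ranking of docking
    binding-energy matrices. A seeded synthetic-data generator emulates the
    compound tables, disease-gene lists, scored interaction edges and
    pathway collections the workflow consumes, so every stage is testable
    offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
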