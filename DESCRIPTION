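Package: msekda
Title: Marker-Set Enrichment and Key Driver Analysis Across Species
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A genetics-driven pipeline for cross-species comparison of
    disease-associated gene sets. Gene sets (pathways or co-expression
    modules) are mapped to GWAS marker space through tissue-specific
    eQTLs with linkage-disequilibrium pruning, scored for enrichment of
    strong GWAS signal with a quantile-cutoff modified chi-square
    statistic calibrated against random-gene-set permutation nulls,
    merged into non-redundant supersets, matched across species via
    ortholog overlap rules (Jaccard and one-sided overlap with
    hypergeometric testing), and interrogated for key driver genes by
    neighborhood enrichment on directed gene-regulatory networks.
    Includes a synthetic-data generator with planted enrichment and
    planted network key drivers so the whole pipeline is testable
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    Matrix,
    igraph,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
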