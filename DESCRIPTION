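Package: quotawatch
Title: Compliance, Adaptiveness and Coverage of Wildlife Trade Export Quotas
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: An end-to-end pipeline for auditing CITES-style national export
    quotas against reported trade. Reads Species+-dialect quota tables (with
    free-text scope notes) and CITES Trade Database-dialect ledgers, cleans
    and deduplicates quota records, parses notes into structured term/source/
    purpose scopes, and computes compliance statistics: percent-of-quota use,
    zero-quota subversion, breach tallies and exporter/importer discrepancy
    tables. Fits a Bayesian hierarchical counterfactual model contrasting
    pre-quota trade trends with post-quota volumes and quota levels, a
    nonlinear change-point (hinge) model of quota-update frequency against
    series length, and quantifies live wild-sourced trade occurring outside
    any quota, crossed with IUCN threat categories. A synthetic-data
    generator emulates all inputs with known ground truth so every stage is
    testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    tibble,
    purrr,
    readr,
    stringr,
    rlang,
    jsonlite,
    rjags,
    coda,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    stringi,
    optparse,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
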