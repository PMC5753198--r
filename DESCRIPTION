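Package: pagnet
Title: Gene-Set Cohesion Scoring, Prioritization and Set-to-Set Networks
Version: 1.0.0
Authors@R: person("PAG", "Analytics", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: An offline analytics engine for collections of gene sets
    (pathways, annotated lists and gene signatures). Scores the internal
    cohesion of each set against a confidence-weighted protein-protein
    interaction network (CoCo), removes the set-size bias by polynomial
    regression in log-log space (nCoCo), ranks genes inside a set with a
    random-walk-with-restart weight combined with corpus membership
    frequency (RP-score), performs hypergeometric gene-list enrichment
    with Benjamini-Hochberg false-discovery control and a configurable
    filter chain, and builds membership-based (m-type) and
    regulation-based (r-type) set-to-set networks with dual hypergeometric
    thresholds. Includes a deterministic synthetic-data generator with
    planted cohesive modules and planted cross-set regulation, plus a
    command-line pipeline interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
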