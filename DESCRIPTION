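Package: ohcnet
Title: Hierarchical-Complexity Curricula and Constructive Network Growth on the Balance-Beam Task
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Generates balance-beam (balance-scale) problems segregated by
    Order of Hierarchical Complexity (counting, sum, multiplication,
    distributive-law problems), trains minimal feedforward networks on each
    subset with an adaptive-learning-rate batch gradient-descent engine and
    seven forward connectivity patterns, searches for the smallest structure
    that solves each subset using an error-weighted efficiency statistic, and
    builds higher-order network structures on top of lower-order ones with
    block-wise learning-rate reduction or freezing so that lower-order
    structures are never overwritten.
License: MIT
Encoding: UTF-8
Imports:
    stats,
    utils,
    yaml,
    jsonlite,
    rlang
Suggests: testthat (>= 3.0.0), withr, optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
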