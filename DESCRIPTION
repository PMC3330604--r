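Package: PartialAlign
Title: Partial Smith-Waterman Alignment for Locating Large Deletions
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Local sequence alignment tools for locating large deletions in
    query sequences. Implements Smith-Waterman alignment with affine gap
    penalties and a similarity-ratio statistic, together with two split-search
    strategies that divide a query into a former and a latter part, align each
    part to the reference separately, and report the deletion boundary and the
    deleted reference interval: an incremental scan over former-part lengths
    and a faster binary-search-style scheme that halves its step each
    iteration. A simulation harness generates two-fragment deletion queries
    from a reference and benchmarks the estimated-deletion-position error
    (EDPE) of the methods across query-length bins.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    Biostrings,
    IRanges,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
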