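Package: fourCcall
Title: Permutation-Based Calling of Significant 4C-Seq Interactions
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Identifies chromosomal regions that contact a fixed viewpoint in
    circular chromosome conformation capture sequencing (4C-Seq) experiments.
    Builds an in-silico restriction-fragment database with per-fragment
    mappability under the 4C library design, assigns aligned reads to
    fragments, and calls significantly enriched sliding windows using a
    permutation scheme in which an empirical false-discovery-rate cutoff is
    computed after every shuffle and the final per-chromosome threshold is
    taken as an order statistic of the cutoff distribution. Significant
    windows are merged into interactions, trimmed, and prioritized as Broad,
    Intermediate or Narrow according to how the window's read mass is spread
    across fragments; replicate call sets can be intersected with retention
    of the broadest category. A seeded generator of fragment maps and
    4C-like overdispersed count tables with distance decay and planted
    interactions supports calibration and end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    Biostrings,
    rtracklayer,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
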