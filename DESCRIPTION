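Package: wwedmr
Title: Differentially Methylated Region Calling by Coverage-Weighted
    Welch Expansion
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Calls differentially methylated regions (DMRs) from
    two-group bisulfite-sequencing cytosine count tables (WGBS/RRBS)
    using the coverage-weighted Welch expansion (WWE) algorithm: a
    per-site Welch t-test on coverage-weighted methylation means with a
    Fisher's-exact fallback for single-replicate designs, greedy region
    expansion with a bounded tolerance for interior non-differential
    sites, shrink-back at termination, and Benjamini-Hochberg adjustment
    of region p-values.  Reads several common methylation count dialects
    (Bismark coverage, Bismark cytosine report, methylKit-style, ENCODE
    bedMethyl-style, generic TSV) with format auto-detection, annotates
    DMRs with nearby genes, and ships a seeded beta-binomial simulator
    with planted DMRs plus directional overlay and precision/recall/F1
    benchmarking utilities.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    data.table,
    GenomicRanges,
    IRanges,
    S4Vectors,
    graphics,
    stats,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
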