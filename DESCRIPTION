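Package: stockscan
Title: Selection Scans, Directional Introgression and Isolation Analysis for
    Coastal Fish Stocks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Windowed genome scans for positive selection (Weir-Cockerham Fst,
    nucleotide diversity log-ratio, Rsb from site-EHH, Tajima's D and a
    rank-probit composite selection score), classification of positively
    selected regions into nearly-fixed, recently-selected and undetermined
    classes, a shared-haplotype-frequency statistic (nSHF/rSHF) that infers
    the direction of introgression between stocks from identity-by-descent
    segment tables, and isolation-by-distance/environment regressions with a
    weighted multiple-regression variance decomposition (commonality,
    dominance and relative-weight indices) with bootstrap confidence
    intervals. Includes a seeded haplotype-panel simulator with planted
    sweeps, planted introgression tracts and a sea-surface-temperature-driven
    geography so the whole pipeline can be exercised end to end on synthetic
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml,
    jsonlite,
    glmnet,
    geosphere,
    IRanges,
    GenomicRanges,
    S4Vectors,
    rtracklayer,
    vcfR,
    optparse
Suggests:
    testthat (>= 3.0.0),
    car
Config/testthat/edition: 3
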