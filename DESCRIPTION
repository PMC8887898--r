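Package: pgcrtools
Title: Calling and Characterising Progestin Control Regions from ChIP-seq,
    Hi-C and Expression Data
Version: 0.9.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Defines Progestin Control Regions (PgCRs) - clusters of at
    least two progesterone-receptor binding sites with consecutive gaps of
    at most 25 kb, supported by a PAX2 binding site and fully contained
    within one topologically associating domain (TAD) - from ChIP-seq peak
    sets, and characterises them. Provides genomic-interval utilities
    (overlap, Venn partition, shuffling, Fisher association, feature
    annotation), GREAT-style basal-plus-extension peak-to-gene association,
    regulated-gene classification, distance/fold-change analysis, a
    resampling gene-set intersection test, Hi-C contact-matrix statistics
    (virtual 4C, A/B compartments, intra-TAD observed/expected enrichment),
    PWM motif scanning with exact score-distribution thresholds, and a
    seeded synthetic-data generator so the whole pipeline is testable
    without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    GenomicRanges,
    IRanges,
    S4Vectors,
    GenomeInfoDb,
    Biostrings,
    rtracklayer,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    knitr,
    optparse
Config/testthat/edition: 3
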