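Package: neurolnc
Title: Integrative Prioritization of Neuronal lncRNAs with CNV Burden and
    ChIRP-seq Occupancy Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: An integrative pipeline for linking long non-coding RNAs to
    neurodevelopmental disease. Nominates candidate lncRNAs from a
    reprogramming expression time course (dynamic-expression filtering,
    histone H3 RIP chromatin-association calling, guilt-by-association
    co-expression with hypergeometric gene-set enrichment and module
    clustering), tests per-locus case/control copy-number-variant burden
    with Fisher exact statistics and focality classification, and performs
    ChIRP-seq downstream analysis (even/odd track merging, replicate
    consensus, high-confidence peak filtering, basal-plus-extension
    regulatory-domain gene assignment, peak annotation) with a
    permutation null for genomic-interval overlap enrichment. A seeded
    synthetic-data module generates every input with planted ground truth
    so the whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    GenomicRanges,
    IRanges,
    S4Vectors,
    jsonlite,
    rtracklayer,
    fgsea
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
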