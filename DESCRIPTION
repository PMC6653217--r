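Package: cistro
Title: Chromatin-State, Enhancer and Regulatory-Network Dynamics Between Cell States
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An integrative epigenome analysis toolkit for comparing two cell
    states (for example a metastatic derivative against its parental cell
    line) from histone-mark ChIP-seq peak calls and expression tables.
    Classifies promoters into Active/Repressive/Poised/None chromatin states
    and relates state transitions to expression fold change; calls distal
    enhancers from H3K27ac, identifies gained and lost enhancers with a
    scaled-Poisson differential test, and stitches enhancers into
    super-enhancers with a rank-ordering inflection-point cutoff; scans
    position weight matrices over cell-specific regulatory elements to build
    TF-target networks and scores TF-TF cooperation by Jaccard index;
    validates marker panels on patient cohorts with non-negative matrix
    factorization clustering, chi-square association and Kaplan-Meier /
    log-rank survival. Ships a seeded synthetic-data generator with ground
    truth for every analysis stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    IRanges,
    GenomicRanges,
    Biostrings,
    survival,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
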