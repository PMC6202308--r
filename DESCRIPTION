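Package: chortools
Title: Quantitative Analysis of Histone Modification Occupancy and
    Restoration on Newly Replicated DNA
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Downstream analysis of ChOR-seq and spike-in (quantitative)
    ChOR-seq experiments, which measure histone post-translational
    modification occupancy specifically on newly replicated DNA. Provides
    binned coverage tracks with RPM, reference-adjusted RPM (RRPM), RPKM,
    percent-of-maximum and z-score normalization; interval operations for
    windowing parental peaks within replicated regions, oriented domain
    borders and parental-to-nascent peak displacement; classification of
    per-window restoration kinetics and inhibitor-induced signal loss with
    replicate concordance; anchor-centred and length-normalized metagene
    profiles, heatmap matrices and Hilbert-curve signal images; and a
    forward simulator of chromatin replication with parental histone
    recycling, two-fold dilution by new histones, locus-specific
    restoration kinetics and a constant exogenous spike-in, emitting reads,
    features and ground truth for end-to-end parameter-recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    GenomicRanges,
    IRanges,
    S4Vectors,
    GenomeInfoDb,
    rtracklayer,
    data.table,
    yaml,
    jsonlite,
    stats,
    utils,
    tools,
    grDevices,
    graphics,
    methods
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
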