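Package: skimprobe
Title: Two-Tier Design and Evaluation of Hybridization-Capture Probe Panels
    from Transcriptomes and Genome Skims
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Toolkit for developing target-enrichment (hybridization capture)
    probe panels for non-model clades. Tier 1 selects putatively single-copy
    nuclear loci from transcriptomes cross-referenced against curated
    single-copy gene lists from reference genomes, deduplicates loci found via
    multiple genomes by reciprocal best hit, and merges in universal,
    published, and functional locus sets. Tier 2 recovers clade-specific
    template sequences from shallow genome-skimming reads by reference-guided
    consensus assembly, selects one to four templates per locus by identity
    clustering, splices partial contigs onto full-length backbones, and
    screens templates against organellar references. Templates are tiled into
    fixed-length capture probes with homopolymer and decoy screening, and a
    final module computes capture-success statistics (on-target fraction,
    per-template recovery, paralog flags, parsimony-informative-site summaries)
    from capture-experiment reads. A seeded simulator generates every input
    the pipeline consumes so all stages are testable without downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    rtracklayer,
    stats,
    stringr,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
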