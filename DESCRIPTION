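Package: polysynt
Title: Microsynteny Analysis Between a Polyploid Genome and a Diploid Template
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A tested pipeline for assessing microsynteny between an
    autopolyploid genome sampled as large-insert (BAC) clones and a diploid
    relative used as an assembly template. Simulates template genomes and
    diverged polyploid clones with known ground truth, deconvolves
    row/column pooled shotgun reads, finds local alignment anchors with
    Karlin-Altschul bit scores, orders and orients contigs against the
    template with AGP output, classifies micro-rearrangements
    (inversions, translocations, duplications), summarizes repeat families
    and microsatellites, and dates species divergence from median
    Nei-Gojobori Ks under a molecular clock.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    rtracklayer,
    data.table,
    Rcpp,
    stats,
    utils,
    tools,
    methods
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    yaml,
    knitr
Config/testthat/edition: 3
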