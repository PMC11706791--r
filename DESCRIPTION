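Package: copearch
Title: Genome Architecture Analyses for a Calanoid Copepod Genome
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Statistical analyses of genome architecture motivated by the
    chromosome-level genome of the calanoid copepod Eurytemora carolleeae:
    per-gene CpG observed/expected ratios as a signature of historical
    gene-body methylation, Kolmogorov-Smirnov and chi-square tests for
    chromosomal clustering of functional gene sets, read-depth and
    synonymous-divergence (NG86 Ks) screens for gene duplication,
    order-level comparative statistics on karyotype and genome size,
    k-mer based genome-size estimation, and a synthetic-genome generator
    that emulates all required inputs for testing and calibration.
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
    jsonlite,
    stats,
    utils,
    methods
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
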