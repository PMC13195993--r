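Package: cnbpmosaic
Title: Long-Read Characterisation of CNBP (CCTG)n Repeat Expansions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis of targeted long-read (nanopore-style) sequencing of the
    myotonic dystrophy type 2 (DM2) repeat locus in intron 1 of CNBP. Extracts
    reads that span the whole expanded repeat region by anchoring both flanks
    with a semi-global edit-distance search, segments each read into classified
    quadruplet-motif runs ((CCTG)n, (TCTG)n, optional NCTG variants) and
    unclassified gaps under run-length and match-ratio thresholds, and
    aggregates per-read annotations into per-sample somatic-mosaicism
    statistics (expansion-length distributions, 3'-TCTG read fractions,
    binned abundance with kernel density, Tukey box statistics) and
    cohort-level diagnostic arithmetic. A synthetic-locus module simulates
    reads with known repeat architecture, length mosaicism and configurable
    substitution/indel errors, providing ground truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    Rcpp,
    stats,
    utils,
    yaml
Suggests:
    Rsamtools,
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
LinkingTo: Rcpp
Config/testthat/edition: 3
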