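Package: peakcoloc
Title: Promoter Colocalization Analysis for ChIP-Seq Peak Sets
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Downstream analysis of ChIP-seq peak sets for promoter-associated
    architectural proteins. Provides genomic-interval overlap and multi-set
    union logic with per-set membership, annotation of peaks to promoter
    windows around transcription start sites with a euchromatin versus
    pericentromeric-heterochromatin partition, position-weight-matrix motif
    scanning with exact background p-value score thresholds, a Monte Carlo
    colocalization test over housekeeping-gene promoter universes with
    Benjamini-Hochberg correction, cross-tabulation of differential
    expression against binding categories, and a synthetic-data generator
    with known ground truth for calibration and power studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    purrr,
    readr,
    rlang,
    ggplot2,
    generics,
    withr,
    stringr,
    Rcpp,
    Biostrings,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    igraph,
    jsonlite,
    optparse,
    yaml
Config/testthat/edition: 3
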