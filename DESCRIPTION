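Package: mirhairpin
Title: Structural and Sequence Determinants of miRNA Hairpin Processing
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Decomposes animal pri-miRNA hairpins into their named structural
    domains (terminal loop region, miRNA duplex, proximal and distal flanking
    domains), attributes nearest-neighbor free energy to each domain from a
    minimum-free-energy fold, scans the UG/UGU/CNNC flanking motifs and scores
    the bulged-GHG basal-stem motif from a lookup table, converts gel band
    intensities into control-normalized cleavage efficiencies, and links the
    features to Drosha/Dicer cleavage and mature miRNA expression with
    rank-correlation and Mann-Whitney statistics. Includes a seeded synthetic
    hairpin cohort generator with planted structural and motif effects so the
    whole pipeline is testable with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    generics,
    dplyr,
    tidyr,
    purrr,
    tibble,
    readr,
    rlang,
    ggplot2,
    withr,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    Biostrings,
    rtracklayer,
    GenomicRanges,
    jsonlite
LinkingTo: Rcpp
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
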