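Package: tmpclust
Title: Single-Gene Phage Cluster Typing, Degenerate Primer Design and
    Alignment-Free Phylogenetics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Toolkit for predicting bacteriophage cluster and subcluster
    membership from a single marker gene (typically the tape measure
    protein, TMP). Provides word-match dotplot comparison and
    classification against a labelled reference panel, global affine-gap
    alignment and progressive multiple alignment with free end gaps,
    conserved-window scanning and degenerate PCR primer design with
    in-silico PCR and cross-reactivity screening, feature-frequency-profile
    (alignment-free) phylogenetics with neighbor-joining, bootstrap
    majority-rule consensus, the Matching Splits tree distance and the
    genealogical sorting index, recovery-accuracy statistics with Wald
    confidence intervals, and a seeded generator of cluster-structured
    mosaic synthetic phage genomes for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ape,
    Biostrings,
    phangorn,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    jsonlite,
    knitr,
    optparse,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
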