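Package: sproutmir
Title: Small RNA Profiling and miRNA Regulatory Networks in Tea Sprouts
Version: 0.1.0
Authors@R: person("Maintainer", "Packages", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: A reusable pipeline for plant small-RNA sequencing studies of
    developing tea (Camellia sinensis) sprouts: read cleaning and tag
    collapsing, structural-RNA annotation, known and novel miRNA
    identification with hairpin-precursor validation, TPM normalization,
    differential expression, developmental trend profiling, rule-based plant
    miRNA target prediction with position-specific mismatch scoring,
    hypergeometric GO/KEGG enrichment with Benjamini-Hochberg FDR, and
    miRNA-TF mRNA-metabolite correlation network construction.  Includes a
    fully specified synthetic-data generator with planted ground truth so the
    whole pipeline is testable without sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    IRanges,
    data.table,
    igraph,
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
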