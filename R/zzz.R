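#' @useDynLib sproutmir, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

.datatable.aware <- TRUE

utils::globalVariables(c(
  ".", "mirna", "transcript", "start", "score", "ratio", "ledger",
  "tag", "count", "class", "mirna_id", "distance", "family", "n_species",
  "conserved", "tissue", "library_id", "log2fc", "pvalue", "significant",
  "term", "namespace", "qvalue", "k", "M", "gene", "metabolite", "mrna",
  "coefficient", "p", "tf_family", "clean_total", "J"
))
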