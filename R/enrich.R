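#' Upper-tail hypergeometric p-value for over-representation
#'
#' P(X >= k) for X ~ Hypergeometric(N, M, n): drawing a study set of size n
#' from a background of N genes of which M carry the term.
#'
#' @param k study hits; @param n study size; @param M background hits;
#' @param N background size.
#' @export
hypergeom_tail <- function(k, n, M, N) {
  if (any(k < 0 | k > n | n > N | M > N | M < 0)) {
    stop("hypergeometric bounds violated: need 0 <= k <= n <= N and 0 <= M <= N")
  }
  stats::phyper(k - 1, M, N - M, n, lower.tail = FALSE)
}

#' Benjamini-Hochberg step-up q-values
#'
#' q_(i) = min over j >= i of p_(j) * m / j, capped at 1; order-preserving in
#' the original p ordering.
#'
#' @param p numeric vector of p-values in \[0, 1\].
#' @export
bh_fdr <- function(p) {
  if (length(p) == 0L) return(numeric(0))
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must lie in [0, 1]")
  m <- length(p)
  ord <- order(p)
  q_sorted <- pmin(1, rev(cummin(rev(p[ord] * m / seq_len(m)))))
  q <- numeric(m)
  q[ord] <- q_sorted
  q
}

#' Term over-representation of a study gene set against a background
#'
#' One upper-tail hypergeometric test per term with at least one study hit;
#' Benjamini-Hochberg q-values are computed within each namespace; results
#' are sorted by p-value.  A term is flagged significant at q <= `q_cutoff`.
#'
#' @param study character vector of study gene ids (must all be in
#'   `background`).
#' @param background character vector of background gene ids (the universe).
#' @param annotation data.frame with columns gene, term, and optionally
#'   namespace and label.
#' @param q_cutoff significance threshold on the q-value (default 0.05).
#' @return data.table (term, namespace, label, k, n, M, N, pvalue, qvalue,
#'   significant).
#' @export
enrich <- function(study, background, annotation, q_cutoff = 0.05) {
  study <- unique(study)
  background <- unique(background)
  missing <- setdiff(study, background)
  if (length(missing) > 0L) {
    stop("study genes absent from background: ", paste(missing, collapse = ", "))
  }
  ann <- as.data.table(annotation)
  if (!"namespace" %in% names(ann)) ann[, namespace := "default"]
  if (!"label" %in% names(ann)) ann[, label := NA_character_]
  ann <- unique(ann[gene %in% background, .(gene, term, namespace, label)])
  N <- length(background)
  n <- length(study)
  res <- ann[, .(k = sum(gene %in% study), M = .N,
                 label = label[1]), by = .(term, namespace)]
  res <- res[k >= 1L]
  if (nrow(res) == 0L) {
    return(data.table(term = character(0), namespace = character(0),
                      label = character(0), k = integer(0), n = integer(0),
                      M = integer(0), N = integer(0), pvalue = numeric(0),
                      qvalue = numeric(0), significant = logical(0)))
  }
  res[, `:=`(n = n, N = N)]
  res[, pvalue := hypergeom_tail(k, n, M, N), by = seq_len(nrow(res))]
  res[, qvalue := bh_fdr(pvalue), by = namespace]
  res[, significant := qvalue <= q_cutoff]
  setorder(res, pvalue)
  res[, .(term, namespace, label, k, n, M, N, pvalue, qvalue, significant)]
}
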