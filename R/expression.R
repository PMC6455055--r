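#' Normalize raw counts to tags-per-million (TPM)
#'
#' TPM = count / total clean tags of the library x 10^6.
#'
#' @param counts numeric matrix, miRNAs as rows, libraries as columns.
#' @param lib_totals numeric vector of per-library clean-tag totals (same
#'   order as the columns); must be positive.
#' @return numeric matrix of TPM values with the same dimnames.
#' @export
tpm_normalize <- function(counts, lib_totals) {
  counts <- as.matrix(counts)
  if (length(lib_totals) != ncol(counts)) {
    stop("need one library total per count column")
  }
  if (any(lib_totals <= 0)) stop("library totals must be positive")
  sweep(counts, 2, lib_totals, "/") * 1e6
}

#' Percentage of a library's clean tags in a class, rounded to 2 decimals
#'
#' @param count class tag total.
#' @param total library clean-tag total.
#' @export
tag_ratio <- function(count, total) {
  if (any(total <= 0)) stop("library totals must be positive")
  round(count / total * 100, 2)
}

#' Pairwise replicate correlations on log2(TPM + 1)
#'
#' Pearson coefficient for every within-tissue replicate pair; pairs with a
#' constant vector are reported as `NA`.
#'
#' @param tpm TPM matrix, miRNAs x libraries.
#' @param tissues tissue label per column.
#' @return data.table (tissue, lib_a, lib_b, r).
#' @export
replicate_correlation <- function(tpm, tissues) {
  stopifnot(ncol(tpm) == length(tissues))
  lt <- log2(tpm + 1)
  libs <- colnames(tpm)
  if (is.null(libs)) libs <- paste0("lib", seq_len(ncol(tpm)))
  out <- list()
  for (ts in unique(as.character(tissues))) {
    idx <- which(tissues == ts)
    if (length(idx) < 2L) next
    for (pair in combn(idx, 2, simplify = FALSE)) {
      a <- lt[, pair[1]]; b <- lt[, pair[2]]
      r <- if (sd(a) == 0 || sd(b) == 0) NA_real_ else cor(a, b)
      out[[length(out) + 1L]] <- data.table(tissue = ts, lib_a = libs[pair[1]],
                                            lib_b = libs[pair[2]], r = r)
    }
  }
  if (length(out) == 0L) stop("need at least two replicates in some tissue")
  data.table::rbindlist(out)
}

#' Differential expression between two library groups
#'
#' Replicate libraries are pooled by summation.  For each miRNA a 2x2 table
#' (miRNA count vs remaining clean tags, group A vs group B) is tested with a
#' doubled one-sided Fisher exact test: the smaller hypergeometric tail
#' probability is doubled and capped at 1.  The fold change is
#' log2((TPM_A + c) / (TPM_B + c)) on group-mean TPM with pseudo-TPM c.  A
#' miRNA is flagged significant when p < `alpha` and |log2FC| >= `lfc`.
#'
#' @param counts_a,counts_b count matrices (miRNAs x replicate libraries) with
#'   identical row order.
#' @param totals_a,totals_b per-library clean-tag totals.
#' @param alpha,lfc significance thresholds (defaults 0.05 and 2).
#' @param pseudo pseudo-TPM added to both group means (default 0.01).
#' @return data.table (mirna, log2fc, pvalue, significant).
#' @export
differential_expression <- function(counts_a, counts_b, totals_a, totals_b,
                                    alpha = 0.05, lfc = 2.0, pseudo = 0.01) {
  counts_a <- as.matrix(counts_a); counts_b <- as.matrix(counts_b)
  stopifnot(nrow(counts_a) == nrow(counts_b),
            ncol(counts_a) >= 1L, ncol(counts_b) >= 1L,
            ncol(counts_a) == length(totals_a),
            ncol(counts_b) == length(totals_b))
  ka <- rowSums(counts_a); kb <- rowSums(counts_b)
  ta <- sum(totals_a); tb <- sum(totals_b)
  tpm_a <- rowMeans(tpm_normalize(counts_a, totals_a))
  tpm_b <- rowMeans(tpm_normalize(counts_b, totals_b))
  log2fc <- log2((tpm_a + pseudo) / (tpm_b + pseudo))
  # X = count drawn for group A from the pooled miRNA tags, margins fixed
  p_low <- stats::phyper(ka, ta, tb, ka + kb)
  p_high <- stats::phyper(ka - 1, ta, tb, ka + kb, lower.tail = FALSE)
  pvalue <- pmin(1, 2 * pmin(p_low, p_high))
  ids <- rownames(counts_a)
  if (is.null(ids)) ids <- paste0("mir", seq_len(nrow(counts_a)))
  data.table(mirna = ids, log2fc = log2fc, pvalue = pvalue,
             significant = pvalue < alpha & abs(log2fc) >= lfc)
}

#' Classify tissue-specific miRNAs
#'
#' A miRNA counts as expressed in a tissue when its raw count is at least
#' `min_count` in at least `min_reps` of that tissue's replicate libraries.
#' It is specific to a class (Bud; Leaf = L1 and L2; Stem = S1 and S2) when it
#' is expressed in at least one tissue of the class and in no tissue outside
#' it.
#'
#' @param counts count matrix, miRNAs x libraries.
#' @param tissues tissue label per column (Bud, L1, L2, S1, S2).
#' @param classes named list mapping class name to its member tissues.
#' @param min_count,min_reps expression presence rule (defaults 1 and 2).
#' @return list with `specific`: named list of miRNA id vectors per class, and
#'   `venn`: table of expression patterns over classes.
#' @export
tissue_specific <- function(counts, tissues,
                            classes = list(Bud = "Bud", Leaf = c("L1", "L2"),
                                           Stem = c("S1", "S2")),
                            min_count = 1L, min_reps = 2L) {
  counts <- as.matrix(counts)
  stopifnot(ncol(counts) == length(tissues))
  ids <- rownames(counts)
  if (is.null(ids)) ids <- paste0("mir", seq_len(nrow(counts)))
  tis <- unique(as.character(tissues))
  expressed <- matrix(FALSE, nrow(counts), length(tis),
                      dimnames = list(NULL, tis))
  for (ts in tis) {
    expressed[, ts] <-
      rowSums(counts[, tissues == ts, drop = FALSE] >= min_count) >= min_reps
  }
  cls_expr <- matrix(FALSE, nrow(counts), length(classes),
                     dimnames = list(NULL, names(classes)))
  for (cl in names(classes)) {
    cls_expr[, cl] <-
      rowSums(expressed[, intersect(classes[[cl]], tis), drop = FALSE]) > 0
  }
  specific <- lapply(names(classes), function(cl) {
    ids[cls_expr[, cl] & rowSums(cls_expr[, setdiff(colnames(cls_expr), cl),
                                          drop = FALSE]) == 0]
  })
  names(specific) <- names(classes)
  pattern <- apply(cls_expr, 1, function(x)
    paste(colnames(cls_expr)[x], collapse = "&"))
  pattern[pattern == ""] <- "none"
  list(specific = specific, venn = table(pattern))
}

# the 8 non-flat step signatures in enumeration order -> profile index 0..7
.trend_profiles <- matrix(c(-1, -1, -1, 0, -1, 1, 0, -1, 0, 1, 1, -1, 1, 0, 1, 1),
                          ncol = 2, byrow = TRUE)

.trend_class <- function(s1, s2) {
  if (s1 == 0 && s2 == 0) return("flat")
  if (s1 == 1 && s2 == -1) return("peak")
  if (s1 == -1 && s2 == 1) return("valley")
  if (s1 <= 0 && s2 <= 0) return("down")
  "up"
}

#' Assign trend profiles over three ordered developmental stages
#'
#' For consecutive stage means m_i, the step is +1 when
#' (m_{i+1} + c) / (m_i + c) >= f, -1 when <= 1/f, else 0.  The two steps give
#' a signature classified as down, up, peak, valley, or flat; flat miRNAs are
#' excluded from the 8 trend profiles (profile index `NA`).
#'
#' @param means numeric matrix (miRNAs x 3 ordered stage means) or a length-3
#'   vector.
#' @param f fold threshold separating a step from flat (default 1.5).
#' @param pseudo pseudocount added to both means of a ratio (default 0.01).
#' @param group optional group label (e.g. "G1") copied into the result.
#' @return data.table (mirna, group, step1, step2, profile, class).
#' @export
assign_trend <- function(means, f = 1.5, pseudo = 0.01, group = NA_character_) {
  if (is.null(dim(means))) means <- matrix(means, nrow = 1)
  stopifnot(ncol(means) == 3L)
  ids <- rownames(means)
  if (is.null(ids)) ids <- paste0("mir", seq_len(nrow(means)))
  step <- function(a, b) {
    r <- (b + pseudo) / (a + pseudo)
    ifelse(r >= f, 1L, ifelse(r <= 1 / f, -1L, 0L))
  }
  s1 <- step(means[, 1], means[, 2])
  s2 <- step(means[, 2], means[, 3])
  profile <- vapply(seq_along(s1), function(i) {
    hit <- which(.trend_profiles[, 1] == s1[i] & .trend_profiles[, 2] == s2[i])
    if (length(hit)) hit - 1L else NA_integer_
  }, 0L)
  cls <- mapply(.trend_class, s1, s2)
  data.table(mirna = ids, group = group, step1 = s1, step2 = s2,
             profile = profile, class = cls)
}

#' Summarize trend assignments into per-profile counts and class percentages
#'
#' Flat assignments are excluded before percentages are computed; percentages
#' are reported to one decimal.
#'
#' @param assignments data.table from [assign_trend()] (rows may repeat).
#' @return list with `profile_counts`, `class_counts` and `class_pct`
#'   data.tables, and `n_assigned` (non-flat total).
#' @export
summarize_trends <- function(assignments) {
  dt <- as.data.table(assignments)[class != "flat"]
  n <- nrow(dt)
  pc <- dt[, .(count = .N), by = profile]
  cc <- dt[, .(count = .N), by = class]
  cc[, pct := round(count / n * 100, 1)]
  setorder(pc, profile)
  setorder(cc, class)
  list(profile_counts = pc, class_counts = cc[, .(class, count)],
       class_pct = cc[, .(class, pct)], n_assigned = n)
}

#' Relative qPCR fold change by the 2^-ddCT method
#'
#' @param ct_target_sample,ct_ref_sample CT of target and reference gene in
#'   the sample.
#' @param ct_target_cal,ct_ref_cal CT of target and reference gene in the
#'   calibrator.
#' @return fold change 2^-((ct_ts - ct_rs) - (ct_tc - ct_rc)), always > 0.
#' @export
ddct <- function(ct_target_sample, ct_ref_sample, ct_target_cal, ct_ref_cal) {
  stopifnot(is.finite(ct_target_sample), is.finite(ct_ref_sample),
            is.finite(ct_target_cal), is.finite(ct_ref_cal))
  2^-((ct_target_sample - ct_ref_sample) - (ct_target_cal - ct_ref_cal))
}
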