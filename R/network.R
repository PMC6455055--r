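#' Annotate genes with transcription-factor families from a lookup table
#'
#' @param genes character vector of gene ids.
#' @param tf_table data.frame (gene, family) or TSV path; a gene listed with
#'   conflicting families is an error.
#' @return data.table (gene, tf_family) for the annotated subset; genes absent
#'   from the table are dropped.
#' @export
tf_annotate <- function(genes, tf_table) {
  if (is.character(tf_table) && length(tf_table) == 1L) tf_table <- read_tsv(tf_table)
  tf <- unique(as.data.table(tf_table)[, 1:2])
  data.table::setnames(tf, c("gene", "tf_family"))
  dup <- tf[, .N, by = gene][N > 1L]
  if (nrow(dup) > 0L) {
    stop("conflicting TF families for gene(s): ", paste(dup$gene, collapse = ", "))
  }
  tf[gene %in% genes][order(gene)]
}

.pearson_edge <- function(x, y) {
  n <- length(x)
  r <- cor(x, y)
  tstat <- r * sqrt((n - 2) / (1 - r^2))
  p <- if (abs(r) >= 1) 0 else 2 * pt(-abs(tstat), n - 2)
  c(r = r, p = p)
}

.spearman_exact_p <- function(x, y) {
  # exhaustive permutation two-sided p for |rho|; exact and cheap at n = 5
  rx <- rank(x); ry <- rank(y)
  obs <- abs(cor(rx, ry))
  perms <- .permutations(length(y))
  stats <- apply(perms, 1, function(idx) abs(cor(rx, ry[idx])))
  mean(stats >= obs - 1e-12)
}

.permutations <- function(n) {
  if (n == 1L) return(matrix(1L))
  sub <- .permutations(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(i) {
    cbind(i, sub + (sub >= i))
  }))
}

#' mRNA-metabolite edges by Pearson correlation over tissues
#'
#' Pearson r over matched tissue profiles with a two-sided p-value from the
#' t transform on n - 2 degrees of freedom; an edge is kept when |r| > `r_min`
#' and p < `alpha`.  Zero-variance profiles are skipped with a message.
#'
#' @param mrna numeric matrix, genes x tissues (tissue means).
#' @param metabolites numeric matrix, metabolites x tissues, same tissue
#'   order.
#' @param r_min,alpha thresholds (defaults 0.9 and 0.05).
#' @return data.table (mrna, metabolite, coefficient, p, method).
#' @export
mrna_metabolite_edges <- function(mrna, metabolites, r_min = 0.9, alpha = 0.05) {
  mrna <- as.matrix(mrna); metabolites <- as.matrix(metabolites)
  stopifnot(ncol(mrna) == ncol(metabolites))
  out <- list()
  for (g in rownames(mrna)) {
    if (sd(mrna[g, ]) == 0) {
      message("zero-variance profile skipped: ", g)
      next
    }
    for (mt in rownames(metabolites)) {
      if (sd(metabolites[mt, ]) == 0) next
      e <- .pearson_edge(mrna[g, ], metabolites[mt, ])
      if (abs(e["r"]) > r_min && e["p"] < alpha) {
        out[[length(out) + 1L]] <- data.table(
          mrna = g, metabolite = mt, coefficient = unname(e["r"]),
          p = unname(e["p"]), method = "Pearson")
      }
    }
  }
  if (length(out) == 0L) {
    return(data.table(mrna = character(0), metabolite = character(0),
                      coefficient = numeric(0), p = numeric(0),
                      method = character(0)))
  }
  data.table::rbindlist(out)
}

#' miRNA-mRNA edges by negative Spearman correlation over tissues
#'
#' Spearman rho on average ranks with a two-sided p-value from the
#' t-approximation (or the exhaustive permutation null, exact at n = 5); an
#' edge is kept when rho <= `rho_max` and p < `alpha`.
#'
#' @param mirna numeric matrix, miRNAs x tissues (TPM tissue means).
#' @param mrna numeric matrix, genes x tissues, same tissue order.
#' @param rho_max,alpha thresholds (defaults -0.5 and 0.05).
#' @param p_method "t" (default) or "exact".
#' @return data.table (mirna, mrna, coefficient, p, method).
#' @export
mirna_mrna_edges <- function(mirna, mrna, rho_max = -0.5, alpha = 0.05,
                             p_method = c("t", "exact")) {
  p_method <- match.arg(p_method)
  mirna <- as.matrix(mirna); mrna <- as.matrix(mrna)
  stopifnot(ncol(mirna) == ncol(mrna))
  out <- list()
  for (mi in rownames(mirna)) {
    if (sd(mirna[mi, ]) == 0) {
      message("zero-variance profile skipped: ", mi)
      next
    }
    for (g in rownames(mrna)) {
      if (sd(mrna[g, ]) == 0) next
      rho <- cor(rank(mirna[mi, ]), rank(mrna[g, ]))
      p <- if (p_method == "exact") {
        .spearman_exact_p(mirna[mi, ], mrna[g, ])
      } else {
        n <- ncol(mirna)
        if (abs(rho) >= 1) 0 else {
          tstat <- rho * sqrt((n - 2) / (1 - rho^2))
          2 * pt(-abs(tstat), n - 2)
        }
      }
      if (rho <= rho_max && p < alpha) {
        out[[length(out) + 1L]] <- data.table(
          mirna = mi, mrna = g, coefficient = rho, p = p, method = "Spearman")
      }
    }
  }
  if (length(out) == 0L) {
    return(data.table(mirna = character(0), mrna = character(0),
                      coefficient = numeric(0), p = numeric(0),
                      method = character(0)))
  }
  data.table::rbindlist(out)
}

#' Extract miRNA -> TF-mRNA -> metabolite triplets
#'
#' A triplet is every path miRNA--mRNA--metabolite in which the shared mRNA is
#' TF-annotated; both edge records are carried along.
#'
#' @param mirna_mrna edges from [mirna_mrna_edges()].
#' @param mrna_metabolite edges from [mrna_metabolite_edges()].
#' @param tf data.table from [tf_annotate()] (gene, tf_family).
#' @return data.table (mirna, mrna, tf_family, metabolite, rho, rho_p, r, r_p).
#' @export
extract_triplets <- function(mirna_mrna, mrna_metabolite, tf) {
  mm <- as.data.table(mirna_mrna)
  me <- as.data.table(mrna_metabolite)
  tf <- as.data.table(tf)
  joined <- merge(mm[, .(mirna, mrna, rho = coefficient, rho_p = p)],
                  me[, .(mrna, metabolite, r = coefficient, r_p = p)],
                  by = "mrna", allow.cartesian = TRUE)
  joined <- merge(joined, tf[, .(mrna = gene, tf_family)], by = "mrna")
  if (nrow(joined) == 0L) {
    return(data.table(mirna = character(0), mrna = character(0),
                      tf_family = character(0), metabolite = character(0),
                      rho = numeric(0), rho_p = numeric(0), r = numeric(0),
                      r_p = numeric(0)))
  }
  setorder(joined, mirna, mrna, metabolite)
  joined[, .(mirna, mrna, tf_family, metabolite, rho, rho_p, r, r_p)]
}

#' Export the association network as GraphML and SIF-like TSV
#'
#' Nodes are typed (miRNA, mRNA, metabolite) and edge weights are the
#' correlation coefficients.
#'
#' @param mirna_mrna,mrna_metabolite edge tables.
#' @param graphml_path,sif_path output paths (either may be `NULL`).
#' @return the igraph object, invisibly.
#' @export
export_network <- function(mirna_mrna, mrna_metabolite,
                           graphml_path = NULL, sif_path = NULL) {
  mm <- as.data.table(mirna_mrna)
  me <- as.data.table(mrna_metabolite)
  edges <- rbind(
    mm[, .(from = mirna, to = mrna, weight = coefficient, type = "miRNA-mRNA")],
    me[, .(from = mrna, to = metabolite, weight = coefficient,
           type = "mRNA-metabolite")])
  node_type <- c(setNames(rep("miRNA", nrow(mm)), mm$mirna),
                 setNames(rep("mRNA", nrow(mm)), mm$mrna),
                 setNames(rep("mRNA", nrow(me)), me$mrna),
                 setNames(rep("metabolite", nrow(me)), me$metabolite))
  node_type <- node_type[!duplicated(names(node_type))]
  g <- igraph::graph_from_data_frame(
    edges, directed = FALSE,
    vertices = data.frame(name = names(node_type), type = unname(node_type)))
  if (!is.null(graphml_path)) igraph::write_graph(g, graphml_path, format = "graphml")
  if (!is.null(sif_path)) {
    write_tsv(edges[, .(source = from, interaction = type, target = to,
                        weight = weight)], sif_path)
  }
  invisible(g)
}
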