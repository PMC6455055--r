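test_that("tf_annotate joins on gene id and rejects conflicts", {
  tf <- data.frame(gene = c("CSA031667", "CSA036087"), family = c("SBP", "MYB"))
  got <- tf_annotate(c("CSA031667", "CSA000001"), tf)
  expect_equal(got$gene, "CSA031667")
  expect_equal(got$tf_family, "SBP")
  expect_equal(nrow(tf_annotate("CSA031667", tf[integer(0), ])), 0L)
  expect_equal(nrow(tf_annotate("X", tf)), 0L)
  bad <- rbind(tf, data.frame(gene = "CSA031667", family = "MYB"))
  expect_error(tf_annotate("CSA031667", bad), "conflicting")
})

test_that("Pearson and Spearman match textbook formulas on random vectors", {
  set.seed(71)
  for (i in 1:30) {
    x <- runif(5); y <- runif(5)
    r_ref <- sum((x - mean(x)) * (y - mean(y))) /
      sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
    expect_equal(cor(x, y), r_ref, tolerance = 1e-12)
    rho_ref <- cor(rank(x), rank(y))
    mrna <- matrix(y, 1, dimnames = list("g", NULL))
    mir <- matrix(x, 1, dimnames = list("m", NULL))
    e <- mirna_mrna_edges(mir, mrna, rho_max = 2, alpha = 1.1)
    expect_equal(e$coefficient, rho_ref, tolerance = 1e-12)
  }
})

test_that("mrna_metabolite_edges applies both Pearson thresholds jointly", {
  tissues <- 1:5
  mrna <- matrix(tissues, 1, dimnames = list("g1", NULL))
  met <- matrix(2 * tissues, 1, dimnames = list("GC", NULL))
  e <- mrna_metabolite_edges(mrna, met)
  expect_equal(nrow(e), 1L)
  expect_equal(e$coefficient, 1)
  # orthogonal contrast: r = 0, dropped
  met0 <- matrix(c(-1, 1, 0, 1, -1), 1, dimnames = list("EC", NULL))
  expect_equal(nrow(mrna_metabolite_edges(mrna, met0)), 0L)
  # r computed but both thresholds must hold
  met2 <- matrix(c(1, 2, 3, 4, 4.2), 1, dimnames = list("C", NULL))
  r <- cor(c(1, 2, 3, 4, 5), c(1, 2, 3, 4, 4.2))
  tstat <- r * sqrt(3 / (1 - r^2))
  p <- 2 * pt(-abs(tstat), 3)
  e2 <- mrna_metabolite_edges(mrna, met2)
  expect_equal(nrow(e2), as.integer(abs(r) > 0.9 && p < 0.05))
  # zero-variance profile is skipped with a message
  expect_message(mrna_metabolite_edges(matrix(rep(1, 5), 1,
                                              dimnames = list("flat", NULL)),
                                       met), "zero-variance")
})

test_that("mirna_mrna_edges keeps only significant negative monotone pairs", {
  mir <- matrix(1:5, 1, dimnames = list("m", NULL))
  anti <- matrix(5:1, 1, dimnames = list("g", NULL))
  e <- mirna_mrna_edges(mir, anti)
  expect_equal(e$coefficient, -1)
  expect_equal(nrow(e), 1L)
  # identical profiles: rho = +1, dropped
  expect_equal(nrow(mirna_mrna_edges(mir, matrix(1:5, 1,
                                                 dimnames = list("g", NULL)))), 0L)
  # rho = -0.6 passes the rho rule but fails p; exhaustive permutation oracle
  y <- c(3, 5, 4, 1, 2)  # rho(1:5, y) = -0.6
  expect_equal(cor(rank(1:5), rank(y)), -0.6)
  perms <- gtools_perm <- NULL
  all_perm <- function(v) {
    if (length(v) == 1) return(matrix(v))
    out <- NULL
    for (i in seq_along(v)) {
      sub <- all_perm(v[-i])
      out <- rbind(out, cbind(v[i], sub))
    }
    out
  }
  pm <- all_perm(1:5)
  rhos <- apply(pm, 1, function(idx) cor(rank(1:5), rank(y[idx])))
  p_exact <- mean(abs(rhos) >= 0.6 - 1e-12)
  expect_gt(p_exact, 0.05)
  expect_equal(nrow(mirna_mrna_edges(mir, matrix(y, 1,
                                                 dimnames = list("g", NULL)))), 0L)
  expect_equal(nrow(mirna_mrna_edges(mir, matrix(y, 1,
                                                 dimnames = list("g", NULL)),
                                     p_method = "exact")), 0L)
  # t-approximation and exact permutation agree on keep/drop at defaults
  set.seed(72)
  for (i in 1:20) {
    g <- matrix(runif(5), 1, dimnames = list("g", NULL))
    a <- nrow(mirna_mrna_edges(mir, g))
    b <- nrow(mirna_mrna_edges(mir, g, p_method = "exact"))
    expect_equal(a, b)
  }
})

test_that("edge filtering is threshold-monotone", {
  set.seed(73)
  mir <- matrix(runif(25), 5, dimnames = list(paste0("m", 1:5), NULL))
  mrna <- matrix(runif(25), 5, dimnames = list(paste0("g", 1:5), NULL))
  loose <- mirna_mrna_edges(mir, mrna, rho_max = -0.1, alpha = 1.01)
  tight <- mirna_mrna_edges(mir, mrna, rho_max = -0.8, alpha = 1.01)
  expect_true(all(paste(tight$mirna, tight$mrna) %in%
                  paste(loose$mirna, loose$mrna)))
  met <- matrix(runif(15), 3, dimnames = list(c("GC", "EC", "C"), NULL))
  loose2 <- mrna_metabolite_edges(mrna, met, r_min = 0.1, alpha = 1.01)
  tight2 <- mrna_metabolite_edges(mrna, met, r_min = 0.95, alpha = 1.01)
  expect_true(all(paste(tight2$mrna, tight2$metabolite) %in%
                  paste(loose2$mrna, loose2$metabolite)))
})

test_that("triplets require a TF-annotated bridging mRNA", {
  mm <- data.table(mirna = "m1", mrna = c("g1", "g2"),
                   coefficient = -1, p = 0.01, method = "Spearman")
  me <- data.table(mrna = c("g1", "g2"), metabolite = "theanine",
                   coefficient = 0.99, p = 0.001, method = "Pearson")
  tf <- data.table(gene = "g1", tf_family = "MYB")
  tri <- extract_triplets(mm, me, tf)
  expect_equal(nrow(tri), 1L)
  expect_equal(tri$mrna, "g1")
  expect_equal(tri$tf_family, "MYB")
  # no negative miRNA-mRNA edges -> empty triplet list
  tri2 <- extract_triplets(mm[integer(0)], me, tf)
  expect_equal(nrow(tri2), 0L)
})

test_that("network export writes GraphML and SIF with typed nodes", {
  mm <- data.table(mirna = "m1", mrna = "g1", coefficient = -0.9, p = 0.01,
                   method = "Spearman")
  me <- data.table(mrna = "g1", metabolite = "C", coefficient = 0.95,
                   p = 0.01, method = "Pearson")
  gml <- tempfile(fileext = ".graphml")
  sif <- tempfile(fileext = ".tsv")
  g <- export_network(mm, me, gml, sif)
  expect_true(file.exists(gml))
  expect_setequal(igraph::V(g)$type, c("metabolite", "miRNA", "mRNA"))
  expect_equal(igraph::ecount(g), 2)
  out <- read_tsv(sif)
  expect_equal(nrow(out), 2L)
})
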