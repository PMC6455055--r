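test_that("match_known assigns by Hamming distance with tie-breaking", {
  catalog <- c(refB = "UGACAGAAGAGAGUGAGCACA", refA = "UGACAGAAGAGAGUGAGCACA")
  tags <- data.table(tag = "TGACAGAAGAGAGTGAGCACA", count_l1 = 10L)
  mk <- match_known(tags, catalog)
  expect_equal(mk$assignments$distance, 0L)
  expect_equal(mk$assignments$mirna_id, "refA")  # lexicographic tie-break
  # a tag at distance 3 from every reference is unmatched
  far <- "AAACAGAAGAGAGUGAGCACA"  # 2 subs
  far <- sub("A$", "G", far)     # 3rd sub
  mk2 <- match_known(data.table(tag = far, count_l1 = 1L),
                     c(ref = "UGACAGAAGAGAGUGAGCACA"))
  expect_equal(nrow(mk2$assignments), 0L)
  expect_error(match_known(tags, character(0)), "empty")
})

test_that("every 2-substitution variant of a reference matches", {
  ref <- c(ref1 = "UGACAGAAGAGAGUGAGCACA")
  bases <- c("A", "C", "G", "U")
  v <- strsplit(ref[[1]], "")[[1]]
  variants <- character(0)
  for (i in 1:20) {
    for (j in (i + 1):21) {
      for (bi in setdiff(bases, v[i])) {
        for (bj in setdiff(bases, v[j])) {
          w <- v; w[i] <- bi; w[j] <- bj
          variants <- c(variants, paste(w, collapse = ""))
        }
      }
    }
  }
  expect_equal(length(variants), choose(21, 2) * 9)
  tags <- data.table(tag = variants, count_l1 = 1L)
  mk <- match_known(tags, ref)
  expect_equal(nrow(mk$assignments), length(variants))
  expect_true(all(mk$assignments$distance == 2L))
  expect_equal(mk$mirnas$count_l1, length(variants))
})

test_that("match_known equals a brute-force all-pairs Hamming scan", {
  set.seed(51)
  catalog <- setNames(random_rna(20, 21), sprintf("ref%02d", 1:20))
  tags <- random_rna(40, 21)
  # mutate half the tags from catalog entries so there are real matches
  for (i in 1:20) {
    v <- strsplit(catalog[[sample(20, 1)]], "")[[1]]
    pos <- sample(21, sample(0:3, 1))
    for (p in pos) v[p] <- sample(setdiff(c("A", "C", "G", "U"), v[p]), 1)
    tags[i] <- paste(v, collapse = "")
  }
  mk <- match_known(data.table(tag = tags, count_l1 = 1L), catalog)
  hamming <- function(a, b) sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
  for (tg in tags) {
    d <- vapply(catalog, hamming, 0, a = tg)
    expected <- if (min(d) <= 2) names(catalog)[order(d, names(catalog))][1]
                else NA_character_
    got <- mk$assignments$mirna_id[mk$assignments$tag == tg]
    if (is.na(expected)) expect_equal(length(got), 0L)
    else expect_equal(got[1], expected)
  }
})

test_that("call_novel accepts constructed hairpins and rejects unstructured loci", {
  set.seed(52)
  mature <- "TGACAGAAGAGAGTGAGCACA"
  arm5 <- paste0(mature, "GCTAGCTAGC")
  prec <- paste0(arm5, "ATTAATTA",
                 as.character(Biostrings::reverseComplement(
                   Biostrings::DNAString(arm5))))
  pad <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                           collapse = "")
  genome <- setNames(paste0(pad(300), prec, pad(300)), "c1")
  nv <- call_novel(data.table(tag = mature), genome)
  expect_gte(nrow(nv), 1L)
  expect_equal(nv$arm[1], "5p")
  expect_true(all(nv$mfe <= -18))
  expect_match(nv$mirna_id[1], "^novel-m\\d{4}-5p$")
  # mature must be fully contained and paired in the reported precursor
  off <- nv$mature_offset[1]
  expect_equal(substr(nv$precursor[1], off, off + nchar(mature) - 1),
               chartr("T", "U", mature))
  # a poly-A locus folds to nothing and is rejected
  genomeA <- setNames(paste0(pad(300), strrep("A", 21), pad(300)), "c1")
  nvA <- call_novel(data.table(tag = strrep("A", 21)), genomeA)
  expect_equal(nrow(nvA), 0L)
  # locus too close to the contig edge is skipped with a message
  genomeE <- setNames(paste0(mature, pad(300)), "c1")
  expect_message(nvE <- call_novel(data.table(tag = mature), genomeE),
                 "too close")
})

test_that("planted precursors are fully recalled at zero noise", {
  p <- synth_pipeline()
  g <- p$g
  mature_dna <- chartr("U", "T", g$truth$mirnas$mature_seq)
  nv <- call_novel(data.table(tag = mature_dna), g$reference$genome)
  expect_true(all(g$truth$mirnas$mature_seq %in% nv$mature_seq))
  planted <- g$truth$mirnas
  for (i in seq_len(nrow(planted))) {
    hit <- nv[nv$mature_seq == planted$mature_seq[i] & nv$arm == "5p", ]
    expect_gte(nrow(hit), 1L)
  }
})

test_that("conservation summary counts species and is column-permutation invariant", {
  m <- rbind(fam1 = c(1, 1, 0, 1), fam2 = c(0, 0, 0, 0), fam3 = rep(1, 4))
  colnames(m) <- paste0("s", 1:4)
  cs <- conservation_summary(m, threshold = 2)
  expect_equal(cs$n_species, c(3L, 0L, 4L))
  expect_equal(cs$conserved, c(TRUE, FALSE, TRUE))
  perm <- m[, c(3, 1, 4, 2)]
  expect_equal(conservation_summary(perm, threshold = 2), cs)
  expect_error(conservation_summary(m[integer(0), , drop = FALSE]), "empty")
})

test_that("composition bias frequencies are well-formed", {
  cb <- composition_bias(c("ACGU"))
  expect_equal(unname(cb$positional[cbind(c("A", "C", "G", "U"), 1:4)]),
               rep(1, 4))
  cb2 <- composition_bias(c("UAAG", "UGGGA", "UCC"))
  expect_equal(unname(cb2$positional["U", 1]), 1)
  expect_true(all(abs(colSums(cb2$positional) - 1) < 1e-12))
  expect_equal(unname(cb2$first_by_length[, "U"]), rep(1, 3))
  # uniform random sequences: every base near 0.25 at every position
  set.seed(53)
  cb3 <- composition_bias(random_rna(10000, 21))
  expect_true(all(abs(cb3$positional - 0.25) < 0.02))
})
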