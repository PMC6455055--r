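write_fastq_fixture <- function(seqs, quals, path) {
  out <- as.vector(rbind(paste0("@r", seq_along(seqs)), seqs, "+", quals))
  writeLines(out, path)
  path
}

ADAPTER <- "TGGAATTCTCGGGTGCCAAGG"

test_that("clean_reads trims adapters, filters and collapses", {
  mi <- "TGACAGAAGAGAGTGAGCACA"  # 21 nt insert
  fq <- tempfile(fileext = ".fastq")
  write_fastq_fixture(paste0(mi, ADAPTER), strrep("I", nchar(mi) + nchar(ADAPTER)), fq)
  res <- clean_reads(fq, ADAPTER)
  expect_equal(res$tags$tag, mi)
  expect_equal(res$tags$count, 1L)
  # adapter found with one mismatch
  adp2 <- sub("^T", "A", ADAPTER)
  write_fastq_fixture(paste0(mi, adp2), strrep("I", nchar(mi) + nchar(adp2)), fq)
  expect_equal(clean_reads(fq, ADAPTER)$tags$tag, mi)
  # a 12-nt insert is discarded by the length window
  short <- paste0(substr(mi, 1, 12), ADAPTER)
  write_fastq_fixture(short, strrep("I", nchar(short)), fq)
  res <- clean_reads(fq, ADAPTER)
  expect_equal(nrow(res$tags), 0L)
  expect_equal(res$stats$out_of_range, 1L)
  # low mean quality discards the read
  write_fastq_fixture(paste0(mi, ADAPTER), strrep("#", nchar(mi) + nchar(ADAPTER)), fq)
  res <- clean_reads(fq, ADAPTER)
  expect_equal(res$stats$low_quality, 1L)
  expect_equal(nrow(res$tags), 0L)
  # malformed FASTQ errors with a record index
  writeLines(c("@r1", "ACGT", "+", "IIII", "@r2", "ACGT"), fq)
  expect_error(clean_reads(fq, ADAPTER), "record")
})

test_that("collapsed counts conserve the number of surviving reads", {
  set.seed(41)
  mirs <- c("TGACAGAAGAGAGTGAGCACA", "TTGGACTGAAGGGAGCTCCCT", "TGCCTGGCTCCCTGTATGCCA")
  n <- c(400, 350, 250)
  reads <- sample(rep(paste0(mirs, ADAPTER), n))
  fq <- tempfile(fileext = ".fastq")
  write_fastq_fixture(reads, strrep("I", nchar(reads[1])), fq)
  res <- clean_reads(fq, ADAPTER)
  expect_equal(nrow(res$tags), 3L)
  expect_equal(sum(res$tags$count), 1000L)
  expect_equal(res$tags$count[match(mirs, res$tags$tag)], n)
  expect_equal(res$stats$clean_reads, 1000L)
})

test_that("annotation assigns one class per tag in priority order", {
  genome <- setNames(paste(rep("ACGTTGCA", 50), collapse = ""), "chr1")
  substr(genome, 101, 121) <- "TGACAGAAGAGAGTGAGCACA"
  rrna <- "GGGCCCAAATTTGGGCCCAAATTTGGGCCC"
  tags <- data.table(tag = c(substr(rrna, 3, 24),            # rRNA substring
                             "TGACAGAAGAGAGTGAGCACA",        # genome, clean
                             strrep("TCAG", 6)),             # nowhere
                     count_l1 = c(1L, 2L, 3L))
  ann <- annotate_tags(tags, ncrna = list(rRNA = c(r1 = rrna)), genome = genome)
  expect_equal(ann$class, c("rRNA", "clean", "unmapped"))
  # reverse complement receives the same genome-mapped status
  rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString("TGACAGAAGAGAGTGAGCACA")))
  ann2 <- annotate_tags(data.table(tag = rc, count_l1 = 1L),
                        ncrna = list(), genome = genome)
  expect_equal(ann2$class, "clean")
  # exon overlap on the plus strand demotes a clean tag; repeat likewise
  exons <- data.frame(contig = "chr1", start = 90, end = 130)
  ann3 <- annotate_tags(data.table(tag = "TGACAGAAGAGAGTGAGCACA", count_l1 = 1L),
                        ncrna = list(), genome = genome, exons = exons)
  expect_equal(ann3$class, "exon_sense")
  # a minus-strand hit inside an exon is not exon_sense
  ann4 <- annotate_tags(data.table(tag = rc, count_l1 = 1L),
                        ncrna = list(), genome = genome, exons = exons)
  expect_equal(ann4$class, "clean")
  ann5 <- annotate_tags(data.table(tag = rc, count_l1 = 1L),
                        ncrna = list(), genome = genome, repeats = exons)
  expect_equal(ann5$class, "repeat")
  expect_error(annotate_tags(tags, ncrna = list(rRNA = "/no/such/file.fa"),
                             genome = genome), "missing reference")
})

test_that("library summaries average replicates and find the modal length", {
  sm <- library_summary(c(13025496, 13672142, 15543919), rep("Bud", 3))
  expect_equal(sm$mean_clean_tags, 14080519)
  expect_equal(library_summary(42, "L1")$mean_clean_tags, 42)
  expect_equal(length_mode(c(21, 24), c(3, 7)), 24)
  expect_equal(length_mode(c(21, 24), c(7, 7)), 21)  # smallest on ties
})

test_that("class totals partition the clean-tag total", {
  p <- synth_pipeline()
  st <- library_stats(p$ann)
  for (lib in names(p$totals)) {
    expect_equal(sum(st$class_totals[library == lib, total]),
                 unname(p$totals[lib]))
  }
})

test_that("zero-contaminant simulated reads map to the genome completely", {
  cfg <- synthetic_config(seed = 3, n_mirnas = 5, n_transcripts = 5,
                          genome_length = 5000, reads_per_library = 500,
                          contaminant_fraction = 0)
  g <- generate_reference(cfg)
  rd <- simulate_reads(cfg, g$reference, g$truth,
                       out_dir = file.path(tempdir(), "fq0"))
  cl <- clean_reads(rd$files[[1]], cfg$adapter)
  ann <- annotate_tags(cl$tags, ncrna = list(), genome = g$reference$genome)
  expect_true(all(ann$class == "clean"))
  # emission log agrees with collapsed counts
  expect_equal(sum(cl$tags$count), sum(rd$counts[, 1]))
})
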