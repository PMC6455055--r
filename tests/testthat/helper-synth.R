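# shared small synthetic study, built once per test run
.synth_cache <- new.env(parent = emptyenv())

small_config <- function(seed = 7L, ...) {
  synthetic_config(seed = seed, n_mirnas = 10L, n_transcripts = 12L,
                   genome_length = 8000L, reads_per_library = 8000L, ...)
}

# full preprocess + quantify chain on a simulated study; memoised by key
synth_pipeline <- function(key = "default", config = small_config(),
                           fastq_dir = NULL) {
  if (!is.null(.synth_cache[[key]])) return(.synth_cache[[key]])
  dir <- if (is.null(fastq_dir)) file.path(tempdir(), paste0("fq_", key)) else fastq_dir
  g <- generate_reference(config)
  rd <- simulate_reads(config, g$reference, g$truth, out_dir = dir)
  cleaned <- lapply(rd$files, clean_reads, adapter = config$adapter)
  tags <- build_tag_table(lapply(cleaned, `[[`, "tags"))
  totals <- vapply(cleaned, function(x) x$stats$clean_reads, 0)
  nc <- g$reference$ncrna
  ann <- annotate_tags(tags, ncrna = list(
    rRNA = nc[grep("^rRNA", names(nc))], tRNA = nc[grep("^tRNA", names(nc))],
    snRNA = nc[grep("^snRNA", names(nc))],
    snoRNA = nc[grep("^snoRNA", names(nc))]),
    genome = g$reference$genome)
  clean <- ann[ann$class == "clean", ]
  mk <- match_known(clean, g$reference$mature)
  counts <- as.matrix(mk$mirnas, rownames = "mirna_id")
  colnames(counts) <- sub("^count_", "", colnames(counts))
  libs <- names(rd$files)
  counts <- counts[, libs, drop = FALSE]
  out <- list(config = config, g = g, rd = rd, cleaned = cleaned, tags = tags,
              totals = totals[libs], ann = ann, clean = clean, mk = mk,
              counts = counts, tissue_of = rep(TISSUES, each = config$n_reps))
  .synth_cache[[key]] <- out
  out
}

random_rna <- function(n, len) {
  vapply(seq_len(n), function(i)
    paste(sample(c("A", "C", "G", "U"), len, replace = TRUE), collapse = ""), "")
}
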