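#' Tissue order used throughout the package
#' @export
TISSUES <- c("Bud", "L1", "L2", "S1", "S2")

#' Metabolites quantified per tissue (mg/g)
#' @export
METABOLITES <- c("GC", "EGC", "C", "EGCG", "EC", "ECG", "caffeine", "theanine")

.SIGNATURES <- list(c(-1L, -1L), c(-1L, 0L), c(-1L, 1L), c(0L, -1L),
                    c(0L, 1L), c(1L, -1L), c(1L, 0L), c(1L, 1L))

random_dna <- function(n, len) {
  vapply(seq_len(n), function(i)
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = ""), "")
}

#' Build a synthetic-study configuration
#'
#' Describes a fully specified toy study: 5 tissues (Bud, L1, L2, S1, S2) with
#' 3 replicates each, miRNAs with planted trend signatures, transcripts with
#' planted target sites, and transcript-metabolite links.  Defaults emulate a
#' desk-scale version of a 15-library sprout sRNA design: overdispersed
#' negative-binomial counts (the zero-dispersion limit gives exact recovery),
#' a 6-fold expression step between consecutive stages, and a 10% structural
#' RNA contaminant fraction.
#'
#' @param seed integer RNG seed; a fixed seed gives byte-identical outputs.
#' @param n_mirnas,n_transcripts,genome_length,reads_per_library study size.
#' @param n_reps replicates per tissue.
#' @param adapter 3' sequencing adapter (DNA).
#' @param mirna_len,transcript_length sequence lengths (nt).
#' @param step_fold expression fold change for one trend step.
#' @param dispersion negative-binomial dispersion (0 = deterministic counts).
#' @param contaminant_fraction fraction of rRNA/tRNA reads per library.
#' @param metabolite_noise_sd Gaussian noise on metabolite contents (mg/g).
#' @param planted_profiles named list mirna id -> list(g1 =, g2 =) step
#'   signatures; defaults cycle through the 8 non-flat signatures.
#' @param planted_targets data.frame (mirna, transcript, start); defaults pair
#'   miRNA i with transcript i at a fixed offset.
#' @param planted_metabolite_links data.frame (transcript, metabolite, sign);
#'   defaults link the planted TF transcripts of strictly rankable miRNAs to
#'   the 8 metabolites with alternating sign.
#' @return object of class `synthetic_config`.
#' @export
synthetic_config <- function(seed = 1L, n_mirnas = 12L, n_transcripts = 16L,
                             genome_length = 60000L, reads_per_library = 20000L,
                             n_reps = 3L, adapter = "TGGAATTCTCGGGTGCCAAGG",
                             mirna_len = 21L, transcript_length = 600L,
                             step_fold = 6, dispersion = 0.05,
                             contaminant_fraction = 0.1,
                             metabolite_noise_sd = 2,
                             planted_profiles = NULL, planted_targets = NULL,
                             planted_metabolite_links = NULL) {
  stopifnot(n_mirnas >= 0L, n_transcripts >= 0L, n_reps >= 1L,
            reads_per_library > 0L, step_fold > 1,
            contaminant_fraction >= 0, contaminant_fraction < 1)
  mirna_ids <- if (n_mirnas > 0L) sprintf("syn-miR%03d", seq_len(n_mirnas))
               else character(0)
  tx_ids <- if (n_transcripts > 0L) sprintf("TX%04d", seq_len(n_transcripts))
            else character(0)
  if (is.null(planted_profiles) && n_mirnas > 0L) {
    planted_profiles <- lapply(seq_len(n_mirnas), function(i) {
      list(g1 = .SIGNATURES[[(i - 1L) %% 8L + 1L]],
           g2 = .SIGNATURES[[(i + 2L) %% 8L + 1L]])
    })
    names(planted_profiles) <- mirna_ids
  }
  if (is.null(planted_targets) && n_mirnas > 0L && n_transcripts > 0L) {
    k <- min(n_mirnas, n_transcripts)
    planted_targets <- data.table(
      mirna = mirna_ids[seq_len(k)], transcript = tx_ids[seq_len(k)],
      start = 101L + (seq_len(k) - 1L) * 7L)
  }
  cfg <- structure(list(
    seed = as.integer(seed), n_tissues = 5L, tissues = TISSUES,
    n_reps = as.integer(n_reps), n_mirnas = as.integer(n_mirnas),
    n_transcripts = as.integer(n_transcripts),
    genome_length = as.integer(genome_length),
    reads_per_library = as.integer(reads_per_library),
    adapter = adapter, mirna_len = as.integer(mirna_len),
    transcript_length = as.integer(transcript_length),
    step_fold = step_fold, dispersion = dispersion,
    contaminant_fraction = contaminant_fraction,
    metabolite_noise_sd = metabolite_noise_sd,
    mirna_ids = mirna_ids, tx_ids = tx_ids,
    planted_profiles = planted_profiles, planted_targets = planted_targets,
    planted_metabolite_links = planted_metabolite_links),
    class = "synthetic_config")
  cfg
}

# 5-tissue relative expression multipliers from a profile's step signatures
.profile_multipliers <- function(profile, step_fold) {
  g1 <- cumsum(profile$g1)
  g2 <- cumsum(profile$g2)
  step_fold^c(0, g1[1], g1[2], g2[1], g2[2])
}

.library_names <- function(config) {
  unlist(lapply(config$tissues, function(ts)
    paste0("s", ts, "-", seq_len(config$n_reps))))
}

#' Generate the synthetic reference bundle with planted ground truth
#'
#' Writes (when `out_dir` is given) a genome FASTA with embedded hairpin
#' precursors, a transcript FASTA carrying planted target sites, the mature
#' miRNA catalog (RNA FASTA) with a family/species presence TSV, a structural
#' ncRNA FASTA, GO/KEGG and TF annotation TSVs, an mRNA tissue-expression TSV
#' and a ground-truth JSON.  Every planted target site is re-scored with the
#' target rule set and every planted precursor is re-folded and checked
#' against the hairpin criteria at generation time.
#'
#' @param config a [synthetic_config()].
#' @param out_dir optional output directory (created if needed).
#' @return list with `reference` (genome, transcripts, mature, ncrna,
#'   presence, go, tf, mrna_profiles) and `truth` (a `ground_truth` list).
#' @export
generate_reference <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(config$seed)
  n <- config$n_mirnas
  ext_len <- 10L
  loop_len <- 8L
  prec_len <- 2L * (config$mirna_len + ext_len) + loop_len
  spacing <- prec_len + 300L
  if (n > 0L && config$genome_length < 500L + n * spacing) {
    stop("infeasible config: genome_length ", config$genome_length,
         " too short to place ", n, " precursors (need >= ",
         500L + n * spacing, ")")
  }

  genome <- setNames(random_dna(1L, config$genome_length), "contig1")
  matures <- character(0)
  hairpins <- data.table(mirna_id = character(0), family = character(0),
                         mature_seq = character(0), precursor = character(0),
                         contig = character(0), prec_start = integer(0),
                         prec_end = integer(0), strand = character(0),
                         mature_offset = integer(0))
  crit <- novel_criteria()
  if (n > 0L) {
    mat_dna <- random_dna(n, config$mirna_len)
    for (i in seq_len(n)) {
      arm5 <- paste0(mat_dna[i], random_dna(1L, ext_len))
      loop <- random_dna(1L, loop_len)
      prec_dna <- paste0(arm5, loop, revcomp_dna(arm5))
      fd <- nussinov_fold(dna2rna(prec_dna))
      chk <- .check_hairpin(fd$structure, fd$mfe, 1L, config$mirna_len, crit)
      if (!chk$ok) {
        stop("generated precursor for ", config$mirna_ids[i],
             " fails the hairpin criteria; change the seed")
      }
      ps <- 251L + (i - 1L) * spacing
      pe <- ps + prec_len - 1L
      substr(genome[[1]], ps, pe) <- prec_dna
      hairpins <- rbind(hairpins, data.table(
        mirna_id = config$mirna_ids[i], family = config$mirna_ids[i],
        mature_seq = dna2rna(mat_dna[i]), precursor = dna2rna(prec_dna),
        contig = "contig1", prec_start = ps, prec_end = pe, strand = "+",
        mature_offset = 1L))
    }
    matures <- setNames(dna2rna(mat_dna), config$mirna_ids)
  }

  transcripts <- setNames(random_dna(config$n_transcripts,
                                     config$transcript_length), config$tx_ids)
  targets <- config$planted_targets
  if (!is.null(targets) && nrow(targets) > 0L) {
    targets <- as.data.table(targets)
    for (r in seq_len(nrow(targets))) {
      mi <- targets$mirna[r]; tx <- targets$transcript[r]; st <- targets$start[r]
      site <- revcomp_dna(rna2dna(matures[[mi]]))
      if (st + nchar(site) - 1L > nchar(transcripts[[tx]])) {
        stop("infeasible config: planted site for ", mi, " at ", st,
             " exceeds transcript length")
      }
      substr(transcripts[[tx]], st, st + nchar(site) - 1L) <- site
      sc <- score_site(matures[[mi]], substr(transcripts[[tx]], st,
                                             st + nchar(site) - 1L))
      if (!sc$pass) stop("planted target site for ", mi, " fails rule ",
                         sc$first_failed)
    }
  } else {
    targets <- data.table(mirna = character(0), transcript = character(0),
                          start = integer(0))
  }

  # structural ncRNA references (contaminant source; never embedded in genome)
  ncrna <- setNames(
    random_dna(8L, 150L),
    c("rRNA_1", "rRNA_2", "tRNA_1", "tRNA_2",
      "snRNA_1", "snRNA_2", "snoRNA_1", "snoRNA_2"))

  # family presence matrix across 20 toy species; about half the families
  # broadly conserved
  n_species <- 20L
  if (n > 0L) {
    p_present <- rep(c(0.85, 0.15), length.out = n)
    presence <- t(vapply(seq_len(n), function(i)
      as.integer(runif(n_species) < p_present[i]), integer(n_species)))
    dimnames(presence) <- list(config$mirna_ids, sprintf("species%02d",
                                                         seq_len(n_species)))
  } else {
    presence <- matrix(integer(0), 0, n_species,
                       dimnames = list(NULL, sprintf("species%02d",
                                                     seq_len(n_species))))
  }

  # planted expression: per-tissue proportions so TPM ratios reproduce the
  # planted fold steps exactly after normalization
  if (n > 0L) {
    base <- runif(n, 0.5, 2)
    rel <- t(vapply(seq_len(n), function(i)
      base[i] * .profile_multipliers(config$planted_profiles[[i]],
                                     config$step_fold),
      numeric(5)))
    prop <- sweep(rel, 2, colSums(rel), "/")
    dimnames(prop) <- list(config$mirna_ids, config$tissues)
    true_tpm <- prop * (1 - config$contaminant_fraction) * 1e6
  } else {
    prop <- true_tpm <- matrix(numeric(0), 0, 5,
                               dimnames = list(NULL, config$tissues))
  }

  # mRNA tissue profiles: planted targets anti-monotone to their miRNA,
  # others random
  mrna_profiles <- matrix(runif(config$n_transcripts * 5, 5, 100),
                          config$n_transcripts, 5,
                          dimnames = list(config$tx_ids, config$tissues))
  for (r in seq_len(nrow(targets))) {
    mi_prof <- true_tpm[targets$mirna[r], ]
    mrna_profiles[targets$transcript[r], ] <-
      (max(mi_prof) + min(mi_prof)) - mi_prof
  }

  # metabolite links: planted TF transcripts of miRNAs whose 5-tissue profile
  # has no ties (so rank-based recovery is unambiguous)
  links <- config$planted_metabolite_links
  if (is.null(links) && nrow(targets) > 0L) {
    rankable <- targets$mirna[vapply(targets$mirna, function(mi)
      !anyDuplicated(true_tpm[mi, ]) && !anyDuplicated(mrna_profiles[
        targets$transcript[targets$mirna == mi][1], ]), logical(1))]
    k <- min(length(METABOLITES), length(rankable))
    if (k > 0L) {
      tx_of <- targets$transcript[match(rankable[seq_len(k)], targets$mirna)]
      links <- data.table(transcript = tx_of,
                          metabolite = METABOLITES[seq_len(k)],
                          sign = rep(c(1, -1), length.out = k))
    }
  }
  if (is.null(links)) links <- data.table(transcript = character(0),
                                          metabolite = character(0),
                                          sign = numeric(0))
  links <- as.data.table(links)
  if (nrow(links) > 0L && !all(links$transcript %in% config$tx_ids)) {
    stop("planted metabolite links reference unknown transcripts")
  }

  # TF lookup: every planted target transcript gets a family
  tf_families <- c("SBP", "MYB", "HD-ZIP", "bHLH", "GRF", "NAC", "TCP", "ARF")
  tf <- if (nrow(targets) > 0L) {
    data.table(gene = unique(targets$transcript),
               family = rep(tf_families,
                            length.out = length(unique(targets$transcript))))
  } else data.table(gene = character(0), family = character(0))

  # GO-style annotation: one planted term on the target transcripts, random
  # background terms elsewhere
  go <- if (config$n_transcripts > 0L) {
    bg_terms <- data.table(
      gene = rep(config$tx_ids, 2L),
      term = sample(sprintf("GO:%07d", 1:10),
                    2L * config$n_transcripts, replace = TRUE),
      namespace = "BP", label = "background process")
    planted <- if (nrow(targets) > 0L) data.table(
      gene = unique(targets$transcript), term = "GO:9999999",
      namespace = "BP", label = "planted enriched process") else NULL
    unique(rbind(bg_terms, planted))
  } else data.table(gene = character(0), term = character(0),
                    namespace = character(0), label = character(0))

  # expected DE sets per tissue pair, from the planted TPM means
  comparisons <- combn(config$tissues, 2, simplify = FALSE)
  de <- lapply(comparisons, function(pr) {
    if (n == 0L) return(character(0))
    lfc <- log2((true_tpm[, pr[1]] + 0.01) / (true_tpm[, pr[2]] + 0.01))
    config$mirna_ids[abs(lfc) >= 2]
  })
  names(de) <- vapply(comparisons, paste, "", collapse = "_vs_")

  # planted trends, as recovered quantities: signatures of the true TPM means
  trend <- if (n > 0L) rbind(
    assign_trend(true_tpm[, c("Bud", "L1", "L2"), drop = FALSE], group = "G1"),
    assign_trend(true_tpm[, c("Bud", "S1", "S2"), drop = FALSE], group = "G2"))
  else data.table()

  # expected triplets (miRNA -| TF-mRNA -> metabolite)
  edges <- if (nrow(links) > 0L) {
    merge(links, targets, by = "transcript")[, .(mirna, transcript, metabolite)]
  } else data.table(mirna = character(0), transcript = character(0),
                    metabolite = character(0))

  truth <- structure(list(
    mirnas = hairpins, prop = prop, tpm = true_tpm, de = de, trend = trend,
    targets = targets, mrna_profiles = mrna_profiles,
    metabolite_links = links, edges = edges), class = "ground_truth")

  reference <- list(genome = genome, transcripts = transcripts,
                    mature = matures, ncrna = ncrna, presence = presence,
                    go = go, tf = tf, mrna_profiles = mrna_profiles)

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_fasta(genome, file.path(out_dir, "genome.fa"))
    write_fasta(transcripts, file.path(out_dir, "transcripts.fa"))
    write_fasta(matures, file.path(out_dir, "mature.fa"))
    write_fasta(ncrna, file.path(out_dir, "ncrna.fa"))
    write_tsv(data.table(family = rownames(presence), presence),
              file.path(out_dir, "mature_presence.tsv"))
    write_tsv(go, file.path(out_dir, "go_annotation.tsv"))
    write_tsv(tf, file.path(out_dir, "tf_annotation.tsv"))
    write_tsv(data.table(gene = rownames(mrna_profiles), mrna_profiles),
              file.path(out_dir, "mrna_expression.tsv"))
    jsonlite::write_json(
      list(mirnas = hairpins, targets = truth$targets,
           metabolite_links = links, de = de,
           trend = trend, tpm = as.data.frame(true_tpm)),
      file.path(out_dir, "ground_truth.json"), digits = NA, pretty = TRUE)
  }
  list(reference = reference, truth = truth)
}

#' Simulate the 15 small-RNA FASTQ libraries
#'
#' Per library, each miRNA's read count is drawn from a negative binomial
#' around its planted proportion of `reads_per_library` (deterministic in the
#' zero-dispersion limit); reads are the mature sequence with the 3' adapter
#' appended, at uniform high base quality.  A `contaminant_fraction` of reads
#' are substrings of the rRNA/tRNA references, also adapter-appended.
#'
#' @param config a [synthetic_config()].
#' @param reference,truth from [generate_reference()].
#' @param out_dir optional directory for FASTQ files (one per library).
#' @return list with `counts`: emitted miRNA read counts (miRNAs x
#'   libraries), `contaminants`: contaminant reads per library, and `files`:
#'   written FASTQ paths (or `NULL`).
#' @export
simulate_reads <- function(config, reference, truth, out_dir = NULL) {
  stopifnot(inherits(config, "synthetic_config"),
            inherits(truth, "ground_truth"))
  set.seed(config$seed + 1000L)
  libs <- .library_names(config)
  tissue_of <- rep(config$tissues, each = config$n_reps)
  n <- config$n_mirnas
  counts <- matrix(0L, n, length(libs),
                   dimnames = list(config$mirna_ids, libs))
  n_contam <- as.integer(round(config$reads_per_library *
                               config$contaminant_fraction))
  contam_src <- reference$ncrna[grepl("^(rRNA|tRNA)", names(reference$ncrna))]
  files <- if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    setNames(file.path(out_dir, paste0(libs, ".fastq")), libs)
  } else NULL

  for (li in seq_along(libs)) {
    ts <- tissue_of[li]
    mu <- truth$prop[, ts] * config$reads_per_library *
      (1 - config$contaminant_fraction)
    cnt <- if (n == 0L) integer(0) else if (config$dispersion == 0) {
      as.integer(round(mu))
    } else {
      rnbinom(n, mu = mu, size = 1 / config$dispersion)
    }
    if (n > 0L) counts[, li] <- cnt
    if (!is.null(files)) {
      seqs <- character(0); ids <- character(0)
      if (n > 0L && sum(cnt) > 0L) {
        seqs <- rep(paste0(rna2dna(reference$mature), config$adapter), cnt)
        ids <- paste0(libs[li], "_", rep(config$mirna_ids, cnt), "_",
                      sequence(cnt))
      }
      if (n_contam > 0L && length(contam_src) > 0L) {
        src <- sample(length(contam_src), n_contam, replace = TRUE)
        off <- vapply(src, function(s)
          sample.int(nchar(contam_src[[s]]) - 24L + 1L, 1L), 0L)
        cseq <- paste0(substr(contam_src[src], off, off + 23L), config$adapter)
        seqs <- c(seqs, cseq)
        ids <- c(ids, paste0(libs[li], "_contam_", seq_len(n_contam)))
      }
      write_fastq_records(ids, seqs, files[[li]])
    }
  }
  list(counts = counts, contaminants = n_contam, files = files)
}

#' Simulate the tissue x metabolite content table (mg/g)
#'
#' Each linked metabolite is an affine transform of its planted transcript's
#' tissue profile (slope sign from the link) rescaled into a 5-85 mg/g range,
#' plus Gaussian noise; unlinked metabolites are uniform random contents.
#'
#' @param config a [synthetic_config()].
#' @param truth from [generate_reference()].
#' @param out_dir optional directory for `metabolites.tsv`.
#' @return numeric matrix, metabolites x 5 tissues (non-negative).
#' @export
simulate_metabolites <- function(config, truth, out_dir = NULL) {
  stopifnot(inherits(config, "synthetic_config"),
            inherits(truth, "ground_truth"))
  set.seed(config$seed + 2000L)
  met <- matrix(runif(length(METABOLITES) * 5, 5, 85), length(METABOLITES), 5,
                dimnames = list(METABOLITES, config$tissues))
  links <- truth$metabolite_links
  for (r in seq_len(nrow(links))) {
    prof <- truth$mrna_profiles[links$transcript[r], ]
    raw <- links$sign[r] * prof
    scaled <- (raw - min(raw)) / (max(raw) - min(raw)) * 80 + 5
    met[links$metabolite[r], ] <- scaled
  }
  if (config$metabolite_noise_sd > 0 && nrow(links) > 0L) {
    idx <- rownames(met) %in% links$metabolite
    met[idx, ] <- met[idx, ] +
      rnorm(sum(idx) * 5, 0, config$metabolite_noise_sd)
  }
  met[met < 0] <- 0
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_tsv(data.table(metabolite = rownames(met), met),
              file.path(out_dir, "metabolites.tsv"))
  }
  met
}
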