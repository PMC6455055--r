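#' Match collapsed tags against a reference catalog of mature miRNAs
#'
#' Ungapped equal-length comparison of each tag against every reference mature
#' of the same length; a tag matches when its Hamming distance to the
#' reference is at most `max_mismatch`.  Each matching tag is assigned to the
#' reference at minimum distance (ties broken by lexicographically smallest
#' reference id) and the counts of all tags assigned to one reference are
#' aggregated.
#'
#' @param tags data.frame/data.table with a `tag` column (DNA or RNA) and one
#'   or more numeric count columns.
#' @param catalog named character vector of mature reference sequences (RNA),
#'   or a FASTA path.
#' @param max_mismatch maximum Hamming distance (default 2).
#' @return list with `mirnas`: data.table of mirna_id plus aggregated count
#'   columns, and `assignments`: data.table (tag, mirna_id, distance).
#' @export
match_known <- function(tags, catalog, max_mismatch = 2L) {
  if (is.character(catalog) && length(catalog) == 1L && file.exists(catalog)) {
    catalog <- read_fasta(catalog)
  }
  if (length(catalog) == 0L) stop("empty reference catalog")
  tags <- as.data.table(tags)
  count_cols <- setdiff(names(tags), c("tag", "class"))
  tag_seqs <- toupper(dna2rna(tags$tag))
  cat_seqs <- toupper(dna2rna(catalog))
  cat_ids <- names(catalog)

  best_id <- rep(NA_character_, length(tag_seqs))
  best_d <- rep(NA_integer_, length(tag_seqs))
  cat_by_len <- split(seq_along(cat_seqs), nchar(cat_seqs))
  tag_by_len <- split(seq_along(tag_seqs), nchar(tag_seqs))
  for (len in intersect(names(tag_by_len), names(cat_by_len))) {
    ti <- tag_by_len[[len]]
    ci <- cat_by_len[[len]]
    tm <- do.call(rbind, strsplit(tag_seqs[ti], ""))
    cm <- do.call(rbind, strsplit(cat_seqs[ci], ""))
    # order references by id so the first minimum is the lexicographic winner
    ord <- order(cat_ids[ci])
    ci <- ci[ord]
    cm <- cm[ord, , drop = FALSE]
    for (a in seq_along(ti)) {
      d <- rowSums(cm != matrix(tm[a, ], nrow(cm), ncol(cm), byrow = TRUE))
      j <- which.min(d)
      if (d[j] <= max_mismatch) {
        best_id[ti[a]] <- cat_ids[ci[j]]
        best_d[ti[a]] <- as.integer(d[j])
      }
    }
  }
  hit <- !is.na(best_id)
  assignments <- data.table(tag = tags$tag[hit], mirna_id = best_id[hit],
                            distance = best_d[hit])
  if (any(hit)) {
    counts <- tags[hit, lapply(.SD, sum), by = .(mirna_id = best_id[hit]),
                   .SDcols = count_cols]
  } else {
    counts <- data.table(mirna_id = character(0))
    for (cc in count_cols) counts[[cc]] <- numeric(0)
  }
  setorder(counts, mirna_id)
  list(mirnas = counts, assignments = assignments)
}

#' Default novel-miRNA hairpin acceptance criteria
#'
#' Thresholds bracket the precursor ranges typical of plant novel-miRNA
#' calls: MFE at most -18 kcal/mol, precursor length 65-400 nt, at least 14 of
#' the mature's bases paired, no more than 6 consecutive unpaired mature
#' bases, and the mature entirely on one arm outside the terminal loop.
#'
#' @param mfe_max,len_min,len_max,min_paired,max_consec_unpaired,flank_short,flank_long
#'   acceptance thresholds and the short/long flanking-window sizes used to
#'   build candidate precursors around a mapped tag locus.
#' @export
novel_criteria <- function(mfe_max = -18, len_min = 65, len_max = 400,
                           min_paired = 14, max_consec_unpaired = 6,
                           flank_short = 20, flank_long = 200) {
  list(mfe_max = mfe_max, len_min = len_min, len_max = len_max,
       min_paired = min_paired, max_consec_unpaired = max_consec_unpaired,
       flank_short = flank_short, flank_long = flank_long)
}

# evaluate hairpin criteria for a folded precursor with the mature at
# positions [mstart, mend]; returns list(ok, arm, n_paired)
.check_hairpin <- function(structure, mfe, mstart, mend, criteria) {
  n <- nchar(structure)
  fail <- function() list(ok = FALSE, arm = NA_character_, n_paired = NA_integer_)
  if (mfe > criteria$mfe_max) return(fail())
  if (n < criteria$len_min || n > criteria$len_max) return(fail())
  partner <- pair_table(structure)
  mp <- partner[mstart:mend]
  n_paired <- sum(mp > 0)
  if (n_paired < criteria$min_paired) return(fail())
  runs <- rle(mp == 0)
  if (any(runs$values & runs$lengths > criteria$max_consec_unpaired)) return(fail())
  paired_to <- mp[mp > 0]
  if (all(paired_to > mend)) {
    arm <- "5p"
  } else if (all(paired_to < mstart)) {
    arm <- "3p"
  } else {
    return(fail())  # mature spans the terminal loop
  }
  list(ok = TRUE, arm = arm, n_paired = n_paired)
}

#' Call novel miRNAs from genome-mapped unannotated tags
#'
#' For each genome locus of each tag, two candidate precursor windows are
#' extracted (short flank upstream/long downstream and the reverse
#' arrangement), folded with `fold_fun`, and accepted if the hairpin criteria
#' hold; the best-MFE accepted candidate per locus is reported.  Loci too
#' close to a contig edge are skipped with a message.
#'
#' @param tags data.frame/data.table with `tag` column (clean, unmatched tags).
#' @param genome named character vector of contig sequences (DNA) or FASTA
#'   path.
#' @param fold_fun folding provider with the [nussinov_fold()] contract.
#' @param criteria list from [novel_criteria()].
#' @return data.table: one row per accepted locus with novel mirna id, family,
#'   mature sequence (RNA), arm, contig, precursor start/end (1-based),
#'   strand, mature offset within the precursor, precursor sequence,
#'   dot-bracket structure and MFE.
#' @export
call_novel <- function(tags, genome, fold_fun = nussinov_fold,
                       criteria = novel_criteria()) {
  if (is.character(genome) && length(genome) == 1L && file.exists(genome)) {
    genome <- read_fasta(genome)
  }
  tags <- as.data.table(tags)
  gss <- Biostrings::DNAStringSet(toupper(rna2dna(genome)))
  out <- list()
  seen <- character(0)
  for (tg in tags$tag) {
    hits <- .genome_hits(tg, gss)
    if (nrow(hits) == 0L) next
    for (h in seq_len(nrow(hits))) {
      contig <- hits$contig[h]
      clen <- nchar(genome[[contig]])
      key <- paste(contig, hits$start[h], hits$end[h], hits$strand[h])
      if (key %in% seen) next
      seen <- c(seen, key)
      wins <- list(c(criteria$flank_short, criteria$flank_long),
                   c(criteria$flank_long, criteria$flank_short))
      best <- NULL
      for (w in wins) {
        if (hits$strand[h] == "+") {
          ps <- hits$start[h] - w[1]; pe <- hits$end[h] + w[2]
        } else {
          ps <- hits$start[h] - w[2]; pe <- hits$end[h] + w[1]
        }
        if (ps < 1L || pe > clen) {
          message("locus ", contig, ":", hits$start[h], "-", hits$end[h],
                  " too close to contig edge; candidate skipped")
          next
        }
        prec_dna <- substr(genome[[contig]], ps, pe)
        if (hits$strand[h] == "-") prec_dna <- revcomp_dna(prec_dna)
        prec <- toupper(dna2rna(prec_dna))
        mstart <- if (hits$strand[h] == "+") hits$start[h] - ps + 1L
                  else pe - hits$end[h] + 1L
        mend <- mstart + nchar(tg) - 1L
        fd <- fold_fun(prec)
        chk <- .check_hairpin(fd$structure, fd$mfe, mstart, mend, criteria)
        if (chk$ok && (is.null(best) || fd$mfe < best$mfe)) {
          best <- list(mfe = fd$mfe, structure = fd$structure, prec = prec,
                       arm = chk$arm, mstart = mstart, ps = ps, pe = pe)
        }
      }
      if (!is.null(best)) {
        out[[length(out) + 1L]] <- data.table(
          mature_seq = toupper(dna2rna(tg)), arm = best$arm, contig = contig,
          prec_start = best$ps, prec_end = best$pe, strand = hits$strand[h],
          mature_offset = best$mstart, precursor = best$prec,
          structure = best$structure, mfe = best$mfe)
      }
    }
  }
  if (length(out) == 0L) {
    return(data.table(mirna_id = character(0), family = character(0),
                      mature_seq = character(0), arm = character(0),
                      contig = character(0), prec_start = integer(0),
                      prec_end = integer(0), strand = character(0),
                      mature_offset = integer(0), precursor = character(0),
                      structure = character(0), mfe = numeric(0)))
  }
  res <- data.table::rbindlist(out)
  res[, family := sprintf("novel-m%04d", seq_len(.N))]
  res[, mirna_id := paste0(family, "-", arm)]
  data.table::setcolorder(res, c("mirna_id", "family"))
  res[]
}

#' Per-family species counts and conservation flags
#'
#' @param presence integer/logical matrix, families as rows, species as
#'   columns (see [read_presence_matrix()]).
#' @param threshold a family is flagged conserved when present in more than
#'   `threshold` species (default 10).
#' @return data.table: family, n_species, conserved.
#' @export
conservation_summary <- function(presence, threshold = 10L) {
  if (nrow(presence) == 0L) stop("empty presence matrix")
  if (anyDuplicated(rownames(presence))) stop("duplicate family rows")
  data.table(family = rownames(presence),
             n_species = as.integer(rowSums(presence > 0)),
             conserved = rowSums(presence > 0) > threshold)
}

#' Positional and first-nucleotide composition of a miRNA set
#'
#' @param seqs character vector of mature sequences (RNA; T read as U).
#' @return list with `positional`: 4 x maxlen matrix of A/C/G/U frequencies
#'   among sequences long enough to cover each position (columns sum to 1),
#'   and `first_by_length`: length-class x base frequency matrix of the first
#'   nucleotide.
#' @export
composition_bias <- function(seqs) {
  if (length(seqs) == 0L) stop("need at least one sequence")
  seqs <- toupper(dna2rna(seqs))
  bases <- c("A", "C", "G", "U")
  maxlen <- max(nchar(seqs))
  chars <- strsplit(seqs, "")
  pos <- matrix(0, 4, maxlen, dimnames = list(bases, seq_len(maxlen)))
  for (p in seq_len(maxlen)) {
    at <- vapply(chars, function(x) if (length(x) >= p) x[p] else NA_character_, "")
    at <- at[!is.na(at)]
    pos[, p] <- tabulate(match(at, bases), 4) / length(at)
  }
  first <- vapply(chars, `[`, "", 1L)
  lens <- nchar(seqs)
  fb <- t(vapply(sort(unique(lens)), function(l) {
    f <- first[lens == l]
    tabulate(match(f, bases), 4) / length(f)
  }, numeric(4)))
  dimnames(fb) <- list(sort(unique(lens)), bases)
  list(positional = pos, first_by_length = fb)
}
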