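# exact genome matching of one tag (both strands) against a DNAStringSet;
# returns data.table(contig, start, end, strand) of every hit
.genome_hits <- function(tag, genome_set) {
  tag_dna <- toupper(rna2dna(tag))
  pats <- list(`+` = Biostrings::DNAString(tag_dna),
               `-` = Biostrings::reverseComplement(Biostrings::DNAString(tag_dna)))
  out <- list()
  for (strand in names(pats)) {
    for (ci in seq_along(genome_set)) {
      m <- Biostrings::matchPattern(pats[[strand]], genome_set[[ci]])
      if (length(m) > 0L) {
        out[[length(out) + 1L]] <- data.table(
          contig = names(genome_set)[ci],
          start = BiocGenerics::start(m), end = BiocGenerics::end(m),
          strand = strand)
      }
    }
  }
  if (length(out) == 0L) {
    return(data.table(contig = character(0), start = integer(0),
                      end = integer(0), strand = character(0)))
  }
  data.table::rbindlist(out)
}

# leftmost position at which the adapter starts in `seq`, allowing
# `max_mismatch` substitutions against the corresponding adapter prefix;
# 0 if the adapter is not found
.find_adapter <- function(seq, adapter, max_mismatch = 1L) {
  n <- nchar(seq)
  la <- nchar(adapter)
  sc <- strsplit(seq, "")[[1]]
  ac <- strsplit(adapter, "")[[1]]
  for (i in seq_len(n)) {
    len <- min(n - i + 1L, la)
    if (sum(sc[i:(i + len - 1L)] != ac[seq_len(len)]) <= max_mismatch) return(i)
  }
  0L
}

#' Clean raw small-RNA reads and collapse them to unique tags
#'
#' Reads are dropped when their mean Phred quality is below `min_qual`; the 3'
#' adapter is then trimmed by exact-prefix search (leftmost occurrence,
#' allowing 1 mismatch, no indels); reads whose insert falls outside
#' `[min_len, max_len]` are discarded; survivors are collapsed to unique tags
#' with counts.  Reads with no detectable adapter are kept untrimmed (the
#' length window then removes full-length non-insert reads).
#'
#' @param fastq path to a FASTQ file (Phred+33).
#' @param adapter 3' adapter sequence (DNA).
#' @param min_len,max_len insert length window (default 18-30 nt).
#' @param min_qual minimum mean base quality (default 20).
#' @return list with `tags`: data.table (tag, count) sorted by tag, and
#'   `stats`: list(raw_reads, low_quality, no_insert, out_of_range, clean_reads).
#' @export
clean_reads <- function(fastq, adapter, min_len = 18L, max_len = 30L,
                        min_qual = 20) {
  rec <- read_fastq_records(fastq)
  raw <- length(rec$seq)
  if (raw == 0L) {
    return(list(tags = data.table(tag = character(0), count = integer(0)),
                stats = list(raw_reads = 0L, low_quality = 0L, no_insert = 0L,
                             out_of_range = 0L, clean_reads = 0L)))
  }
  mq <- vapply(rec$qual, mean, 0)
  ok <- mq >= min_qual
  low_quality <- sum(!ok)
  seqs <- toupper(rec$seq[ok])
  adapter <- toupper(rna2dna(adapter))

  # trim on unique sequences only, then map back through the count table
  tab <- table(seqs)
  uniq <- names(tab)
  pos <- vapply(uniq, .find_adapter, 0L, adapter = adapter)
  insert <- ifelse(pos > 0L, substr(uniq, 1L, pos - 1L), uniq)
  len <- nchar(insert)
  keep <- len >= min_len & len <= max_len
  out_of_range <- sum(as.integer(tab)[!keep])
  dt <- data.table(tag = insert[keep], count = as.integer(tab)[keep])
  dt <- dt[, .(count = sum(count)), by = tag]
  setorder(dt, tag)
  list(tags = dt,
       stats = list(raw_reads = raw, low_quality = low_quality,
                    no_insert = 0L, out_of_range = out_of_range,
                    clean_reads = sum(dt$count)))
}

#' Merge per-library tag tables into one wide TagTable
#'
#' @param tag_lists named list of data.tables (tag, count), one per library.
#' @return data.table with a `tag` column and one `count_<library>` column per
#'   library (absent tags get 0).
#' @export
build_tag_table <- function(tag_lists) {
  stopifnot(length(names(tag_lists)) == length(tag_lists))
  wide <- NULL
  for (lib in names(tag_lists)) {
    dt <- as.data.table(tag_lists[[lib]])[, .(tag, count)]
    data.table::setnames(dt, "count", paste0("count_", lib))
    wide <- if (is.null(wide)) dt else merge(wide, dt, by = "tag", all = TRUE)
  }
  for (cc in setdiff(names(wide), "tag")) {
    data.table::set(wide, which(is.na(wide[[cc]])), cc, 0L)
  }
  setorder(wide, tag)
  wide[]
}

#' Annotate tags by structural-RNA class, exon/repeat overlap and genome match
#'
#' Each tag receives exactly one class, assigned by first match in the
#' priority order rRNA > tRNA > snRNA > snoRNA > exon_sense > repeat > clean >
#' unmapped.  Structural-RNA matching is exact substring of the reference (the
#' tag or its reverse complement); genome mapping is exact match with 0
#' mismatches on either strand (multi-mapping tags are retained).  Exon
#' removal applies to sense-strand (plus-strand) genome hits only; repeat
#' removal applies to hits on either strand.
#'
#' @param tags data.table with a `tag` column (from [build_tag_table()]).
#' @param ncrna named list of character vectors (or FASTA paths) with elements
#'   among rRNA, tRNA, snRNA, snoRNA.
#' @param genome named character vector of contigs (DNA) or FASTA path.
#' @param exons,repeats optional data.frames (contig, start, end), 1-based
#'   inclusive coordinates on the plus strand.
#' @return the tag table with a `class` column added, plus a `hits` attribute
#'   holding genome hit coordinates of clean tags.
#' @export
annotate_tags <- function(tags, ncrna = list(), genome, exons = NULL,
                          repeats = NULL) {
  looks_like_path <- function(x) {
    is.character(x) && length(x) == 1L && !grepl("^[ACGTUNacgtun]+$", x)
  }
  if (looks_like_path(genome)) {
    if (!file.exists(genome)) stop("missing reference file: ", genome)
    genome <- read_fasta(genome)
  }
  ncrna <- lapply(ncrna, function(x) {
    if (looks_like_path(x)) {
      if (!file.exists(x)) stop("missing reference file: ", x)
      read_fasta(x)
    } else x
  })
  tags <- data.table::copy(as.data.table(tags))
  gss <- Biostrings::DNAStringSet(toupper(rna2dna(genome)))

  # structural RNA references as single haystack strings per class
  haystacks <- lapply(ncrna, function(seqs) {
    seqs <- toupper(rna2dna(seqs))
    paste(c(seqs, revcomp_dna(seqs)), collapse = "\n")
  })
  overlaps <- function(hits, iv) {
    if (is.null(iv) || nrow(hits) == 0L) return(FALSE)
    iv <- as.data.table(iv)
    any(vapply(seq_len(nrow(hits)), function(i) {
      nrow(iv[contig == hits$contig[i] & start <= hits$end[i] &
                end >= hits$start[i]]) > 0L
    }, logical(1)))
  }

  cls <- character(nrow(tags))
  hit_list <- vector("list", nrow(tags))
  order_nc <- intersect(c("rRNA", "tRNA", "snRNA", "snoRNA"), names(haystacks))
  for (i in seq_len(nrow(tags))) {
    tg <- toupper(rna2dna(tags$tag[i]))
    assigned <- NA_character_
    for (nc in order_nc) {
      if (grepl(tg, haystacks[[nc]], fixed = TRUE)) { assigned <- nc; break }
    }
    if (is.na(assigned)) {
      hits <- .genome_hits(tg, gss)
      hit_list[[i]] <- hits
      if (nrow(hits) == 0L) {
        assigned <- "unmapped"
      } else if (overlaps(hits[strand == "+"], exons)) {
        assigned <- "exon_sense"
      } else if (overlaps(hits, repeats)) {
        assigned <- "repeat"
      } else {
        assigned <- "clean"
      }
    }
    cls[i] <- assigned
  }
  tags[, class := cls]
  attr(tags, "hits") <- hit_list
  tags[]
}

#' Per-library class totals and tag-length histogram
#'
#' @param tag_table annotated tag table from [annotate_tags()].
#' @return list with `class_totals`: data.table (library, class, total), and
#'   `length_hist`: data.table (library, length, total).
#' @export
library_stats <- function(tag_table) {
  tt <- as.data.table(tag_table)
  count_cols <- grep("^count_", names(tt), value = TRUE)
  long <- data.table::melt(tt, id.vars = intersect(c("tag", "class"), names(tt)),
                           measure.vars = count_cols,
                           variable.name = "library", value.name = "count")
  long[, library := sub("^count_", "", library)]
  cls <- long[, .(total = sum(count)), by = .(library, class)]
  lh <- long[, .(total = sum(count)), by = .(library, length = nchar(tag))]
  setorder(cls, library, class)
  setorder(lh, library, length)
  list(class_totals = cls, length_hist = lh)
}

#' Mean clean-tag totals per replicate group
#'
#' Arithmetic mean of the replicate clean-tag totals per tissue, rounded to
#' the nearest integer.
#'
#' @param clean_totals numeric vector of per-library clean-tag totals.
#' @param tissues character/factor of the same length giving each library's
#'   tissue group.
#' @return data.table (tissue, mean_clean_tags).
#' @export
library_summary <- function(clean_totals, tissues) {
  stopifnot(length(clean_totals) == length(tissues), length(tissues) >= 1L)
  dt <- data.table(total = clean_totals, tissue = as.character(tissues))
  out <- dt[, .(mean_clean_tags = round(mean(total))), by = tissue]
  out[]
}

#' Modal tag length of a library
#'
#' @param lengths integer vector of tag lengths.
#' @param counts matching tag counts.
#' @return the length with the largest total count (smallest on ties).
#' @export
length_mode <- function(lengths, counts) {
  dt <- data.table(length = lengths, count = counts)
  agg <- dt[, .(total = sum(count)), by = length]
  setorder(agg, -total, length)
  agg$length[1]
}
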