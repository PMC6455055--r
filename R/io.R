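#' @importFrom data.table fread fwrite data.table as.data.table setorder :=
#' @importFrom stats rnbinom rnorm runif setNames cor pt sd
#' @importFrom utils combn head
NULL

# DNA <-> RNA alphabet helpers.  Sequencing artefacts (genome, reads,
# transcripts) are kept in DNA; mature miRNAs in RNA, as in miRBase.
dna2rna <- function(x) chartr("Tt", "Uu", x)
rna2dna <- function(x) chartr("Uu", "Tt", x)

revcomp_dna <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Read a FASTA file as a named character vector
#' @param path FASTA file.
#' @export
read_fasta <- function(path) {
  ss <- Biostrings::readBStringSet(path)
  setNames(as.character(ss), names(ss))
}

#' Write named sequences to FASTA
#' @param seqs named character vector.
#' @param path output file.
#' @export
write_fasta <- function(seqs, path) {
  ss <- Biostrings::BStringSet(seqs)
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}

#' Read a tab-separated table with a header row
#' @param path TSV file.
#' @export
read_tsv <- function(path) {
  fread(path, sep = "\t", header = TRUE, data.table = TRUE)
}

#' Write a tab-separated table with a header row
#' @param x data.frame.
#' @param path output file.
#' @export
write_tsv <- function(x, path) {
  fwrite(x, path, sep = "\t", quote = FALSE)
  invisible(path)
}

#' Read a miRNA-family presence/absence matrix
#'
#' Expects a TSV whose first column identifies either families or species and
#' whose remaining columns are 0/1 (or "+"/"-") presence calls.  Returned with
#' families as rows and species as columns, the orientation used by
#' [conservation_summary()].
#'
#' @param path TSV file.
#' @param species_rows if `TRUE` (default) the file has one row per species
#'   and one column per family, and is transposed on the way in.
#' @export
read_presence_matrix <- function(path, species_rows = TRUE) {
  tab <- fread(path, sep = "\t", header = TRUE, data.table = FALSE)
  ids <- tab[[1]]
  m <- as.matrix(tab[, -1, drop = FALSE])
  if (is.character(m)) m <- (m == "+") + 0L
  mode(m) <- "integer"
  rownames(m) <- ids
  if (species_rows) m <- t(m)
  if (anyDuplicated(rownames(m))) stop("duplicate family rows in presence matrix")
  m
}

# Read FASTQ (Phred+33); returns list(seq = character, qual = list of integer
# vectors).  Errors mention the offending record index.
read_fastq_records <- function(path) {
  lines <- readLines(path)
  if (length(lines) %% 4L != 0L) {
    stop("unreadable FASTQ '", path, "': truncated at record ",
         length(lines) %/% 4L + 1L)
  }
  n <- length(lines) %/% 4L
  if (n == 0L) return(list(seq = character(0), qual = list()))
  idx <- seq_len(n)
  hdr <- lines[(idx - 1L) * 4L + 1L]
  sep <- lines[(idx - 1L) * 4L + 3L]
  bad <- which(!startsWith(hdr, "@") | !startsWith(sep, "+"))
  if (length(bad) > 0L) {
    stop("unreadable FASTQ '", path, "': malformed record ", bad[1])
  }
  seqs <- lines[(idx - 1L) * 4L + 2L]
  quals <- lines[(idx - 1L) * 4L + 4L]
  bad <- which(nchar(seqs) != nchar(quals))
  if (length(bad) > 0L) {
    stop("unreadable FASTQ '", path, "': sequence/quality length mismatch in record ",
         bad[1])
  }
  list(seq = seqs, qual = lapply(quals, function(q) utf8ToInt(q) - 33L))
}

write_fastq_records <- function(ids, seqs, path, qual_char = "I") {
  qual <- vapply(nchar(seqs), function(n) strrep(qual_char, n), "")
  out <- as.vector(rbind(paste0("@", ids), seqs, "+", qual))
  writeLines(out, path)
  invisible(path)
}
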