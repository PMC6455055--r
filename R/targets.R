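#' Align a miRNA against an equal-length candidate target site
#'
#' Ungapped antiparallel duplex: position i of the miRNA (counted from its
#' 5' end) is paired against position L - i + 1 of the site, where the site is
#' the transcript subsequence read 5' to 3' on the sense strand.  Each
#' position is classified as a Watson-Crick pair (A:U, G:C), a G:U wobble, or
#' a mismatch.
#'
#' @param mirna miRNA sequence, 5' to 3' (RNA; T is read as U).
#' @param site transcript subsequence of the same length (DNA or RNA).
#' @return object of class `duplex_alignment`: list with `mirna`, `site`,
#'   `states` (character vector over "WC"/"GU"/"MM", indexed by miRNA
#'   position) and `ledger` (compact string, W/G/M per position).
#' @export
align_duplex <- function(mirna, site) {
  mirna <- toupper(dna2rna(mirna))
  site <- toupper(dna2rna(site))
  if (nchar(mirna) != nchar(site)) {
    stop("miRNA and site must have equal length (ungapped duplex)")
  }
  m <- strsplit(mirna, "")[[1]]
  s <- rev(strsplit(site, "")[[1]])  # s[i] faces miRNA position i
  if (!all(c(m, s) %in% c("A", "C", "G", "U"))) {
    stop("non-RNA character in duplex input")
  }
  key <- paste0(m, s)
  states <- ifelse(key %in% c("AU", "UA", "GC", "CG"), "WC",
                   ifelse(key %in% c("GU", "UG"), "GU", "MM"))
  structure(list(mirna = mirna, site = site, states = states,
                 ledger = paste(c(WC = "W", GU = "G", MM = "M")[states],
                                collapse = "")),
            class = "duplex_alignment")
}

#' Default plant target-prediction rule parameters
#'
#' Mismatch weights are 1.0 for a mismatch, 0.5 for a G:U wobble, 0 for a
#' Watson-Crick pair.  The six rules are: (R1) total weight <= `total_max`;
#' (R2) no run of 3 or more consecutive non-WC positions; (R3) no two
#' consecutive non-WC positions within miRNA positions 2-12; (R4) positions 10
#' and 11 must be Watson-Crick; (R5) summed weight over positions 1-12 <=
#' `seed_max`; (R6) duplex/perfect MFE ratio >= `min_energy_ratio` percent.
#'
#' `gu_in_adjacency` controls whether G:U wobbles count as non-WC inside the
#' adjacency/position rules R2-R4 (strict reading, default) or only mismatches
#' do; the weight-based rules R1/R5 always count G:U as 0.5.
#'
#' @param total_max,seed_max,min_energy_ratio,gu_weight,gu_in_adjacency rule
#'   parameters as described above.
#' @export
target_rules <- function(total_max = 4, seed_max = 2.5, min_energy_ratio = 60,
                         gu_weight = 0.5, gu_in_adjacency = TRUE) {
  list(total_max = total_max, seed_max = seed_max,
       min_energy_ratio = min_energy_ratio, gu_weight = gu_weight,
       gu_in_adjacency = gu_in_adjacency)
}

#' Score a duplex alignment against the positional mismatch rules R1-R5
#'
#' @param alignment a `duplex_alignment` from [align_duplex()].
#' @param rules list from [target_rules()].
#' @return list with `total` (mismatch score in half-units), `seed_total`
#'   (positions 1-12), and `verdicts`, a named logical vector over R1..R5.
#' @export
score_rules <- function(alignment, rules = target_rules()) {
  stopifnot(inherits(alignment, "duplex_alignment"))
  st <- alignment$states
  L <- length(st)
  w <- ifelse(st == "MM", 1, ifelse(st == "GU", rules$gu_weight, 0))
  adj <- if (rules$gu_in_adjacency) st != "WC" else st == "MM"
  seed <- seq_len(min(12L, L))

  runs <- rle(adj)
  r2 <- !any(runs$values & runs$lengths >= 3L)
  in212 <- seq_len(L) >= 2L & seq_len(L) <= 12L
  pair_adj <- if (L >= 2L) adj[-L] & adj[-1L] & in212[-L] & in212[-1L] else logical(0)
  r3 <- !any(pair_adj)
  r4 <- all(!adj[intersect(c(10L, 11L), seq_len(L))])

  verdicts <- c(R1 = sum(w) <= rules$total_max,
                R2 = r2, R3 = r3, R4 = r4,
                R5 = sum(w[seed]) <= rules$seed_max)
  list(total = sum(w), seed_total = sum(w[seed]), verdicts = verdicts)
}

#' Duplex minimum-free-energy ratio (rule R6)
#'
#' The duplex energy sums the per-pair energies of the Watson-Crick and G:U
#' positions of the alignment (mismatches contribute 0); the reference energy
#' is the same model applied to the miRNA bound to its exact complement.  Both
#' sides use the package energy model (see [nussinov_fold()]) so the ratio is
#' well defined under one consistent provider.
#'
#' @param alignment a `duplex_alignment`.
#' @return ratio in percent (`NA` if the perfect-complement energy is 0, in
#'   which case the site fails R6).
#' @export
energy_ratio <- function(alignment) {
  stopifnot(inherits(alignment, "duplex_alignment"))
  m <- strsplit(alignment$mirna, "")[[1]]
  s <- rev(strsplit(toupper(dna2rna(alignment$site)), "")[[1]])
  e <- rna_pair_energy(m, s)
  e[alignment$states == "MM"] <- 0
  duplex <- sum(e)
  perfect <- sum(ifelse(m %in% c("G", "C"), -3, -2))
  if (perfect == 0) return(NA_real_)
  100 * duplex / perfect
}

#' Score one candidate site under all six rules
#'
#' @param mirna,site equal-length sequences as in [align_duplex()].
#' @param rules list from [target_rules()].
#' @return list with `pass`, `first_failed` (`NA` if passing), `total`,
#'   `ratio`, `ledger` and the individual rule `verdicts` (R1..R6).
#' @export
score_site <- function(mirna, site, rules = target_rules()) {
  aln <- align_duplex(mirna, site)
  sc <- score_rules(aln, rules)
  ratio <- energy_ratio(aln)
  r6 <- !is.na(ratio) && ratio >= rules$min_energy_ratio
  verdicts <- c(sc$verdicts, R6 = r6)
  failed <- names(verdicts)[!verdicts]
  list(pass = all(verdicts),
       first_failed = if (length(failed)) failed[1] else NA_character_,
       total = sc$total, ratio = ratio, ledger = aln$ledger,
       verdicts = verdicts)
}

# vectorized rule scan of one miRNA over one transcript; returns a data.table
# of passing sites.  Kept independent of score_site() so the two routes can
# be cross-checked.
.scan_transcript <- function(mirna, tx, rules) {
  code <- c(A = 1L, C = 2L, G = 3L, U = 4L)
  m <- code[strsplit(toupper(dna2rna(mirna)), "")[[1]]]
  t <- code[strsplit(toupper(dna2rna(tx)), "")[[1]]]
  L <- length(m)
  n <- length(t)
  if (n < L) return(NULL)
  # state lookup: 1 = WC, 2 = GU, 3 = MM, indexed by (miRNA base, site base)
  stl <- matrix(3L, 4, 4)
  stl[1, 4] <- stl[4, 1] <- stl[3, 2] <- stl[2, 3] <- 1L
  stl[3, 4] <- stl[4, 3] <- 2L
  enl <- matrix(0, 4, 4)
  enl[3, 2] <- enl[2, 3] <- -3
  enl[1, 4] <- enl[4, 1] <- -2
  enl[3, 4] <- enl[4, 3] <- -1
  starts <- seq_len(n - L + 1L)
  # site base facing miRNA position i is transcript position start + L - i
  states <- matrix(0L, length(starts), L)
  energy <- matrix(0, length(starts), L)
  for (i in seq_len(L)) {
    sb <- t[starts + L - i]
    states[, i] <- stl[cbind(rep(m[i], length(sb)), sb)]
    energy[, i] <- enl[cbind(rep(m[i], length(sb)), sb)]
  }
  w <- (states == 3L) * 1 + (states == 2L) * rules$gu_weight
  adj <- if (rules$gu_in_adjacency) states != 1L else states == 3L
  total <- rowSums(w)
  seed <- seq_len(min(12L, L))
  seed_total <- rowSums(w[, seed, drop = FALSE])
  r1 <- total <= rules$total_max
  r5 <- seed_total <= rules$seed_max
  r2 <- rep(TRUE, length(starts))
  if (L >= 3L) {
    for (j in seq_len(L - 2L)) {
      r2 <- r2 & !(adj[, j] & adj[, j + 1L] & adj[, j + 2L])
    }
  }
  r3 <- rep(TRUE, length(starts))
  up <- min(11L, L - 1L)
  if (up >= 2L) {
    for (j in 2:up) r3 <- r3 & !(adj[, j] & adj[, j + 1L])
  }
  r4 <- rep(TRUE, length(starts))
  for (j in intersect(c(10L, 11L), seq_len(L))) r4 <- r4 & !adj[, j]
  energy[states == 3L] <- 0
  perfect <- sum(ifelse(m %in% c(2L, 3L), -3, -2))
  ratio <- if (perfect == 0) rep(NA_real_, length(starts)) else
    100 * rowSums(energy) / perfect
  r6 <- !is.na(ratio) & ratio >= rules$min_energy_ratio
  keep <- which(r1 & r2 & r3 & r4 & r5 & r6)
  if (length(keep) == 0L) return(NULL)
  led <- apply(states[keep, , drop = FALSE], 1, function(s)
    paste(c("W", "G", "M")[s], collapse = ""))
  data.table(start = starts[keep], score = total[keep],
             ratio = ratio[keep], ledger = led)
}

#' Predict miRNA target sites on a transcript set
#'
#' Slides each miRNA over every sense-strand position of every transcript and
#' applies the full rule set R1-R6; every passing site is reported, so one
#' transcript may host multiple sites and multiple miRNAs.
#'
#' @param mirnas named character vector of mature miRNA sequences.
#' @param transcripts named character vector of transcript sequences (DNA or
#'   RNA; T read as U), or a path to a FASTA file.
#' @param rules list from [target_rules()].
#' @return data.table with columns mirna, transcript, start (1-based on the
#'   transcript sense strand), score (mismatch half-units), ratio (energy
#'   ratio percent) and ledger (W/G/M string by miRNA position).
#' @export
predict_targets <- function(mirnas, transcripts, rules = target_rules()) {
  if (is.character(transcripts) && length(transcripts) == 1L &&
      file.exists(transcripts)) {
    transcripts <- read_fasta(transcripts)
  }
  stopifnot(length(names(mirnas)) == length(mirnas),
            length(names(transcripts)) == length(transcripts))
  out <- list()
  for (mi in names(mirnas)) {
    for (tx in names(transcripts)) {
      hits <- .scan_transcript(mirnas[[mi]], transcripts[[tx]], rules)
      if (!is.null(hits)) {
        hits[, `:=`(mirna = mi, transcript = tx)]
        out[[length(out) + 1L]] <- hits
      }
    }
  }
  if (length(out) == 0L) {
    return(data.table(mirna = character(0), transcript = character(0),
                      start = integer(0), score = numeric(0),
                      ratio = numeric(0), ledger = character(0)))
  }
  res <- data.table::rbindlist(out)
  res <- unique(res, by = c("mirna", "transcript", "start"))
  setorder(res, mirna, transcript, start)
  res[, .(mirna, transcript, start, score, ratio, ledger)]
}
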