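#' Fold an RNA sequence under the simplified per-pair energy model
#'
#' Minimum-energy secondary structure by Nussinov-style dynamic programming.
#' Pair energies are GC = -3, AU = -2, GU = -1 kcal/mol with a minimum hairpin
#' loop of 3 unpaired bases.  This is deliberately not a nearest-neighbour
#' thermodynamic model: every MFE-based rule in this package is a threshold or
#' a ratio evaluated under one consistent provider, so only relative energies
#' matter.  Any function accepting a `fold_fun` argument can be handed an
#' external thermodynamic engine with the same `(structure, mfe)` contract,
#' but one provider must be used consistently across a run.
#'
#' Ties in the traceback are resolved toward pairing the 5'-most base, so the
#' reported structure is deterministic.
#'
#' @param seq single RNA string over A/C/G/U (case-insensitive).
#' @param min_loop minimum number of unpaired bases in a hairpin loop.
#' @return list with `structure` (dot-bracket string) and `mfe` (kcal/mol,
#'   always <= 0).
#' @examples
#' nussinov_fold("GGGAAACCC")  # (((...))), -9
#' @export
nussinov_fold <- function(seq, min_loop = 3L) {
  stopifnot(is.character(seq), length(seq) == 1L)
  .fold_nussinov_cpp(toupper(seq), as.integer(min_loop))
}

#' Base-pair partner table of a dot-bracket structure
#'
#' @param structure dot-bracket string (only `(`, `)`, `.`).
#' @return integer vector; position i holds the 1-based partner of base i,
#'   or 0 if unpaired.
#' @export
pair_table <- function(structure) {
  ch <- strsplit(structure, "")[[1]]
  partner <- integer(length(ch))
  stack <- integer(0)
  for (i in seq_along(ch)) {
    if (ch[i] == "(") {
      stack <- c(stack, i)
    } else if (ch[i] == ")") {
      if (length(stack) == 0L) stop("unbalanced dot-bracket string")
      j <- stack[length(stack)]
      stack <- stack[-length(stack)]
      partner[i] <- j
      partner[j] <- i
    } else if (ch[i] != ".") {
      stop("invalid character in dot-bracket string: ", ch[i])
    }
  }
  if (length(stack) > 0L) stop("unbalanced dot-bracket string")
  partner
}

#' Pair energy of two RNA bases under the package energy model
#'
#' @param a,b character vectors of single bases (A/C/G/U).
#' @return numeric vector: -3 for G:C, -2 for A:U, -1 for G:U, 0 otherwise.
#' @export
rna_pair_energy <- function(a, b) {
  key <- paste0(toupper(a), toupper(b))
  e <- c(GC = -3, CG = -3, AU = -2, UA = -2, GU = -1, UG = -1)
  out <- unname(e[key])
  out[is.na(out)] <- 0
  out
}
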