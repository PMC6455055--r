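# independent brute-force oracles, kept free of the implementation paths they
# check

# enumerate every valid secondary structure of a short RNA and return the
# minimum energy under the package pair model (GC -3, AU -2, GU -1, loop >= 3)
enumerate_mfe <- function(seq, min_loop = 3L) {
  s <- strsplit(toupper(seq), "")[[1]]
  pe <- function(a, b) {
    key <- paste0(a, b)
    if (key %in% c("GC", "CG")) -3
    else if (key %in% c("AU", "UA")) -2
    else if (key %in% c("GU", "UG")) -1
    else 0
  }
  best <- function(i, j) {
    if (j - i < min_loop + 1L) return(0)
    e <- best(i + 1L, j)
    for (k in (i + min_loop + 1L):j) {
      ek <- pe(s[i], s[k])
      if (ek == 0) next
      inner <- if (k - i - 1L > min_loop) best(i + 1L, k - 1L) else 0
      rest <- if (k < j) best(k + 1L, j) else 0
      e <- min(e, ek + inner + rest)
    }
    e
  }
  best(1L, length(s))
}

# energy of a dot-bracket structure under the same model
structure_energy <- function(seq, structure) {
  s <- strsplit(toupper(seq), "")[[1]]
  partner <- sproutmir::pair_table(structure)
  e <- 0
  for (i in seq_along(s)) {
    if (partner[i] > i) e <- e + sproutmir::rna_pair_energy(s[i], s[partner[i]])
  }
  e
}

# exhaustive hypergeometric upper tail by enumerating every draw of size n
enumerate_hyper_tail <- function(k, n, M, N) {
  draws <- combn(N, n)
  hits <- colSums(draws <= M)  # items 1..M carry the term
  mean(hits >= k)
}

# independent per-site rule check used against predict_targets; plain loops,
# no shared code with the scanner
oracle_site_pass <- function(mirna, site, total_max = 4, seed_max = 2.5,
                             min_ratio = 60) {
  m <- strsplit(chartr("T", "U", toupper(mirna)), "")[[1]]
  t <- rev(strsplit(chartr("T", "U", toupper(site)), "")[[1]])
  L <- length(m)
  state <- character(L)
  for (i in seq_len(L)) {
    p <- paste0(m[i], t[i])
    state[i] <- if (p %in% c("AU", "UA", "GC", "CG")) "W"
                else if (p %in% c("GU", "UG")) "G" else "M"
  }
  w <- ifelse(state == "M", 1, ifelse(state == "G", 0.5, 0))
  if (sum(w) > total_max) return(FALSE)
  run <- 0
  for (i in seq_len(L)) {
    run <- if (state[i] != "W") run + 1 else 0
    if (run >= 3) return(FALSE)
  }
  for (i in 2:11) {
    if (i + 1 <= L && state[i] != "W" && state[i + 1] != "W") return(FALSE)
  }
  if (L >= 10 && state[10] != "W") return(FALSE)
  if (L >= 11 && state[11] != "W") return(FALSE)
  if (sum(w[seq_len(min(12, L))]) > seed_max) return(FALSE)
  emap <- c(A = -2, U = -2, G = -3, C = -3)
  perfect <- sum(emap[m])
  duplex <- 0
  for (i in seq_len(L)) {
    duplex <- duplex + switch(state[i],
      W = if (m[i] %in% c("G", "C")) -3 else -2,
      G = -1, M = 0)
  }
  100 * duplex / perfect >= min_ratio
}
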