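# Independent reference implementations used as oracles. These deliberately
# share no code with the package's C++ alignment engine.

# pure-R affine-gap local alignment score (Gotoh recurrences, full matrices)
sw_score_ref <- function(q, s, mat, gap_open, gap_extend) {
  qa <- strsplit(q, "")[[1]]
  sa <- strsplit(s, "")[[1]]
  m <- length(qa)
  n <- length(sa)
  H <- matrix(0, m + 1, n + 1)
  E <- matrix(-Inf, m + 1, n + 1)
  F <- matrix(-Inf, m + 1, n + 1)
  best <- 0
  for (i in seq_len(m) + 1) {
    for (j in seq_len(n) + 1) {
      E[i, j] <- max(E[i - 1, j] - gap_extend,
                     H[i - 1, j] - gap_open - gap_extend)
      F[i, j] <- max(F[i, j - 1] - gap_extend,
                     H[i, j - 1] - gap_open - gap_extend)
      H[i, j] <- max(0, H[i - 1, j - 1] + mat[qa[i - 1], sa[j - 1]],
                     E[i, j], F[i, j])
      best <- max(best, H[i, j])
    }
  }
  best
}

# true exhaustive enumeration of every local alignment path (tiny inputs
# only); validates sw_score_ref on cases where full enumeration is feasible
sw_score_enum <- function(q, s, mat, gap_open, gap_extend) {
  qa <- strsplit(q, "")[[1]]
  sa <- strsplit(s, "")[[1]]
  m <- length(qa)
  n <- length(sa)
  rec <- function(i, j, last) {
    best <- 0  # stopping here is always allowed
    if (i <= m && j <= n) {
      best <- max(best, mat[qa[i], sa[j]] + rec(i + 1, j + 1, "d"))
    }
    if (i <= m) {
      cost <- if (last == "q") gap_extend else gap_open + gap_extend
      best <- max(best, -cost + rec(i + 1, j, "q"))
    }
    if (j <= n) {
      cost <- if (last == "s") gap_extend else gap_open + gap_extend
      best <- max(best, -cost + rec(i, j + 1, "s"))
    }
    best
  }
  best <- 0
  for (i in seq_len(m)) {
    for (j in seq_len(n)) {
      best <- max(best, rec(i, j, "start"))
    }
  }
  best
}

# strict path-intersection lowest common ancestor of lineage paths
lca_intersection_ref <- function(lineages) {
  paths <- strsplit(lineages, ";", fixed = TRUE)
  prefix <- paths[[1]]
  for (p in paths[-1]) {
    k <- 0
    while (k < min(length(prefix), length(p)) && prefix[k + 1] == p[k + 1]) {
      k <- k + 1
    }
    prefix <- prefix[seq_len(k)]
    if (length(prefix) == 0) break
  }
  paste(prefix, collapse = ";")
}

random_peptide <- function(len) {
  aa <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "L", "K", "M",
          "F", "P", "S", "T", "W", "Y", "V")
  paste(sample(aa, len, TRUE), collapse = "")
}

random_dna <- function(len) {
  paste(sample(c("A", "C", "G", "T"), len, TRUE), collapse = "")
}
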