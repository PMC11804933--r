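# Independent brute-force oracles used across the suite. These deliberately
# take the dumbest correct route (per-nucleotide vectors, direct frequency
# tables, exhaustive enumeration) so they share no code with the package.

# mutual information of two alignment columns by direct frequency counting
oracle_mi_pair <- function(ci, cj) {
  keep <- ci != "-" & cj != "-"
  ci <- ci[keep]; cj <- cj[keep]
  n <- length(ci)
  if (n == 0) return(NA_real_)
  mi <- 0
  for (a in unique(ci)) for (b in unique(cj)) {
    pab <- sum(ci == a & cj == b) / n
    if (pab > 0)
      mi <- mi + pab * log2(pab / ((sum(ci == a) / n) * (sum(cj == b) / n)))
  }
  mi
}

# full MI matrix by looping oracle_mi_pair (diagonal NA, < min_rows NA)
oracle_mi_matrix <- function(seqs, min_rows = 4L) {
  L <- ncol(seqs)
  m <- matrix(NA_real_, L, L)
  for (i in seq_len(L)) for (j in seq_len(L)) {
    if (i == j) next
    keep <- seqs[, i] != "-" & seqs[, j] != "-"
    if (sum(keep) < min_rows) next
    m[i, j] <- oracle_mi_pair(seqs[, i], seqs[, j])
  }
  m
}

# per-nucleotide coverage vector of a site table over [0, len)
oracle_coverage <- function(sites, len) {
  v <- logical(len)
  for (i in seq_len(nrow(sites)))
    if (sites$end[i] > sites$start[i])
      v[(sites$start[i] + 1):sites$end[i]] <- TRUE
  v
}

# upper-tail hypergeometric by exhaustive enumeration of all draws of B
oracle_hyper_ge <- function(nA, nB, nAB, universe) {
  draws <- utils::combn(universe, nB)
  mean(colSums(draws <= nA) >= nAB)
}

# random binding-site set on one gene (possibly several genes)
random_sites <- function(n, gene = "g1", len = 1000, max_w = 30) {
  s <- sample.int(len - max_w, n, replace = TRUE) - 1L
  w <- sample.int(max_w, n, replace = TRUE)
  binding_site_set(rep(gene, n), s, s + w)
}

# standard coevolution test geometry: three width-5 sites per RBP with a
# bijective planted pairing between their columns
coevo_geometry <- function() {
  a_iv <- cbind(start = c(20L, 60L, 100L), end = c(25L, 65L, 105L))
  b_iv <- cbind(start = c(140L, 160L, 180L), end = c(145L, 165L, 185L))
  cols <- function(iv) unlist(mapply(function(s, e) (s + 1L):e,
                                     iv[, 1], iv[, 2], SIMPLIFY = FALSE))
  list(a_iv = a_iv, b_iv = b_iv, a_cols = cols(a_iv), b_cols = cols(b_iv))
}
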