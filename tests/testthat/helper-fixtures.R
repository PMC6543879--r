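# small builders shared across test files

rand_sfs_pair <- function(n = 10L, lambda = 30, L = 1000) {
  sfs_pair(sfs(rpois(n - 1L, lambda / seq_len(n - 1L)), n, L),
           sfs(rpois(n - 1L, 1.4 * lambda / seq_len(n - 1L)), n, L))
}

# brute-force pi / Tajima's D from an explicit haplotype matrix
# (rows = chromosomes, cols = segregating sites, 0 = ancestral)
brute_stats <- function(haps, L = 1) {
  n <- nrow(haps)
  pairs <- utils::combn(n, 2)
  diffs <- apply(pairs, 2, function(p) sum(haps[p[1], ] != haps[p[2], ]))
  pi_total <- mean(diffs)
  S <- sum(colSums(haps) > 0 & colSums(haps) < n)
  i <- seq_len(n - 1)
  a1 <- sum(1 / i); a2 <- sum(1 / i^2)
  b1 <- (n + 1) / (3 * (n - 1)); b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1; c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1; e2 <- c2 / (a1^2 + a2)
  D <- if (S > 0) (pi_total - S / a1) / sqrt(e1 * S + e2 * S * (S - 1)) else NA
  list(pi = pi_total / L, D = D, S = S)
}

# haplotype matrix whose unfolded SFS equals the given counts vector
haps_from_sfs <- function(counts, n) {
  cols <- list()
  for (i in seq_along(counts)) {
    for (k in seq_len(counts[i])) {
      v <- c(rep(1, i), rep(0, n - i))
      cols[[length(cols) + 1]] <- v
    }
  }
  do.call(cbind, cols)
}

# high-precision oracle for the PRF integral via adaptive quadrature
oracle_expected_sfs <- function(gamma, theta, L, n) {
  vapply(seq_len(n - 1L), function(i) {
    f <- function(x) {
      a <- if (abs(gamma) < 1e-12) 1 / x
      else (1 - exp(-gamma * (1 - x))) / ((1 - exp(-gamma)) * x * (1 - x))
      a * x^i * (1 - x)^(n - i)
    }
    theta * L * choose(n, i) *
      stats::integrate(f, 0, 1, rel.tol = 1e-12, abs.tol = 0)$value
  }, numeric(1))
}
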