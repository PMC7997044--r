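# Shared fixture builders.  Everything is generated in code; no data files.

# correlation_matrix with exact block structure: intra-block rho, 0 between
block_correlation <- function(sizes, rho, binning = NULL) {
  lab <- rep(seq_along(sizes), sizes)
  same <- outer(lab, lab, "==")
  C <- ifelse(same, rho, 0)
  diag(C) <- 1
  correlation_matrix(C, binning = binning)
}

# small symmetric correlation-like matrix with noise, clamped and unit-diag
noisy_correlation <- function(n, sd = 0.1, seed = 1) {
  set.seed(seed)
  A <- matrix(stats::rnorm(n * n, sd = sd), n, n)
  C <- (A + t(A)) / 2
  C <- pmin(pmax(C, -0.9), 0.9)
  diag(C) <- 1
  correlation_matrix(C)
}

# partition labels -> domain_solution over all-valid bins
ds <- function(labels) domain_solution(labels)

# direct (slow, independent) evaluation of the per-domain log-likelihood sum
loglik_oracle <- function(labels, C, g) {
  K <- max(labels)
  total <- 0
  for (k in seq_len(K)) {
    idx <- which(labels == k)
    nk <- length(idx)
    ck <- sum(C[idx, idx])
    gk <- g[k]
    total <- total - 0.5 * ((1 + gk) * (nk - gk * ck / (1 + gk * nk)) -
                              nk * log(1 + gk) + log(1 + gk * nk))
  }
  total
}

# brute-force objective minimization used as the annealer oracle
brute_force_best <- function(cm, lambda) {
  exhaustive_minimum(cm, lambda)
}

# raw/balanced contact-map constructors over the internal representation
new_contact_map_for_test <- function(counts, bin_size = 50000L, chrom = "chrT") {
  bn <- genomic_binning(chrom, bin_size, nrow(counts))
  multicd:::new_contact_map(counts, bn, mask = NULL)
}

balanced_map_for_test <- function(values, bin_size = 50000L, chrom = "chrT") {
  bn <- genomic_binning(chrom, bin_size, nrow(values))
  multicd:::new_contact_map(values, bn, mask = NULL, balanced = TRUE,
                            balance_vector = rep(1, nrow(values)))
}

write_tmp <- function(lines) {
  f <- tempfile(fileext = ".txt")
  writeLines(lines, f)
  f
}
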