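#' Random ground-truth partition
#'
#' Contiguous mode places domain boundaries by a Bernoulli process with rate
#' `1 / mean_size` (the first bin is always a boundary), giving geometric
#' domain sizes with the requested mean.  Non-contiguous mode additionally
#' permutes blocks of bins so that domains become non-local (as compartments
#' are).
#'
#' @param N Number of bins.
#' @param mean_size Mean domain size in bins (`1 <= mean_size <= N`).
#' @param contiguous Keep domains contiguous (default `TRUE`).
#' @param block Block length used to shuffle labels in non-contiguous mode
#'   (default `mean_size`).
#' @param seed Optional integer seed.
#' @return A [domain_solution()].
#' @export
random_partition <- function(N, mean_size, contiguous = TRUE, block = NULL,
                             seed = NULL) {
  stopifnot(mean_size >= 1, mean_size <= N)
  .with_seed(seed, {
    newdom <- c(TRUE, stats::runif(N - 1) < 1 / mean_size)
    labels <- cumsum(newdom)
    if (!contiguous) {
      if (is.null(block)) block <- max(1L, round(mean_size))
      nblk <- ceiling(N / block)
      ord <- sample.int(nblk)
      idx <- unlist(lapply(ord, function(b) {
        seq.int((b - 1L) * block + 1L, min(b * block, N))
      }))
      labels <- labels[idx]
    }
    domain_solution(labels)
  })
}

#' Sample genomic-state signals from the (two-level) group model
#'
#' Draws `n_samples` i.i.d. realizations of
#' `x_i = (eps_i + sqrt(g_{s_i}) eta_{s_i} + sqrt(h_{u_i}) xi_{u_i}) /
#' sqrt(1 + g_{s_i} + h_{u_i})`, where `eta` is one standard normal per
#' primary domain per sample, `xi` one per secondary domain, and `eps` one
#' per site — so each `x_i` has unit variance and the expected correlation is
#' `(g delta_ss' + h delta_uu') / (1 + g + h)` off the diagonal.  Omitting
#' `u` gives the single-level model.
#'
#' @param s Primary [domain_solution()].
#' @param g Per-primary-domain strengths (>= 0; recycled if scalar).
#' @param u Optional secondary [domain_solution()] on the same bins.
#' @param h Per-secondary-domain strengths (>= 0; recycled if scalar).
#' @param n_samples Number of samples (>= 2).
#' @param seed Optional integer seed.
#' @return List with `x` (`n_samples x N` matrix over valid bins), `C_hat`
#'   (empirical [correlation_matrix()]), and `C_model` (expected
#'   correlation).
#' @export
sample_signals <- function(s, g, u = NULL, h = 0, n_samples = 400L,
                           seed = NULL) {
  stopifnot(inherits(s, "domain_solution"), n_samples >= 2)
  lab <- .valid_labels(s)
  N <- length(lab)
  Ks <- max(lab)
  g <- rep_len(g, Ks)
  if (any(g < 0)) stop("'g' must be non-negative")
  if (!is.null(u)) {
    if (!identical(s$mask, u$mask)) stop("'s' and 'u' are on different masks")
    ulab <- .valid_labels(u)
    Ku <- max(ulab)
    h <- rep_len(h, Ku)
    if (any(h < 0)) stop("'h' must be non-negative")
  } else {
    ulab <- rep(1L, N)
    h <- 0
  }
  gi <- g[lab]
  hi <- if (is.null(u)) rep(0, N) else h[ulab]
  .with_seed(seed, {
    x <- matrix(0, n_samples, N)
    denom <- sqrt(1 + gi + hi)
    for (t in seq_len(n_samples)) {
      eta <- stats::rnorm(Ks)
      xi <- stats::rnorm(max(ulab))
      eps <- stats::rnorm(N)
      x[t, ] <- (eps + sqrt(gi) * eta[lab] + sqrt(hi) * xi[ulab]) / denom
    }
    C_hat <- stats::cor(x)
    C_hat <- pmin(pmax(C_hat, -1), 1 - 1e-6)
    diag(C_hat) <- 1
    same_s <- outer(lab, lab, "==")
    same_u <- outer(ulab, ulab, "==")
    # exact correlation of the construction; within a shared group the two
    # sites' strengths coincide, so this reduces to the additive form
    # (g + h)/(1 + g + h) for homogeneous strengths
    C_model <- (sqrt(outer(gi, gi)) * same_s + sqrt(outer(hi, hi)) * same_u) /
      sqrt(outer(1 + gi + hi, 1 + gi + hi))
    diag(C_model) <- 1
    # embed into the full (masked) bin space
    full <- function(m) {
      out <- matrix(NA_real_, length(s$mask), length(s$mask))
      out[s$mask, s$mask] <- m
      diag(out) <- 1
      out
    }
    list(x = x,
         C_hat = correlation_matrix(full(C_hat), mask = s$mask),
         C_model = correlation_matrix(full(pmin(C_model, 1 - 1e-6) +
                                             diag(1e-6, N)), mask = s$mask))
  })
}

#' Simulate a raw Hi-C contact map from a correlation matrix
#'
#' Runs the polymer mapping forward: `gamma_ij = 1 / (4 sigma_c (1 - C_ij))`
#' (infinite-stiffness error if any off-diagonal `C_ij = 1`), contact
#' probabilities from the closed-form radial Gaussian integral, then
#' independent `Binomial(n_reads_per_pair, p_ij)` (or Poisson with that mean)
#' read counts per pair, symmetrized.  Diagonal counts are set to
#' `n_reads_per_pair` (self-contact probability 1).
#'
#' @param cm A [correlation_matrix()] with off-diagonal entries < 1.
#' @param n_reads_per_pair Sequencing depth per bin pair.
#' @param sigma_c Variance scale used for the forward map (default 0.25, so
#'   that `C = 0` maps to `gamma = 1`).
#' @param r_c Capture radius (default 1).
#' @param noise `"binomial"` (default) or `"poisson"` count noise.
#' @param seed Optional integer seed.
#' @return A raw contact map whose preprocessing recovers approximately
#'   `cm`.
#' @export
synth_hic <- function(cm, n_reads_per_pair = 1e5, sigma_c = 0.25, r_c = 1,
                      noise = c("binomial", "poisson"), seed = NULL) {
  noise <- match.arg(noise)
  stopifnot(inherits(cm, "correlation_matrix"))
  v <- which(cm$mask)
  Cv <- cm$C[v, v, drop = FALSE]
  off <- row(Cv) != col(Cv)
  if (any(Cv[off] >= 1))
    stop("off-diagonal correlation of 1 implies infinite stiffness")
  gamma <- 1 / (4 * sigma_c * (1 - Cv))
  p <- contact_probability(gamma, r_c = r_c)
  diag(p) <- 1
  nv <- length(v)
  .with_seed(seed, {
    counts <- matrix(0, nv, nv)
    ut <- which(upper.tri(counts))
    draws <- if (noise == "binomial") {
      stats::rbinom(length(ut), size = n_reads_per_pair, prob = p[ut])
    } else {
      stats::rpois(length(ut), lambda = n_reads_per_pair * p[ut])
    }
    counts[ut] <- draws
    counts <- counts + t(counts)
    diag(counts) <- n_reads_per_pair
    N <- length(cm$mask)
    full <- matrix(0, N, N)
    full[v, v] <- counts
    binning <- if (!is.null(cm$binning)) cm$binning else
      genomic_binning("chr?", 50000L, N)
    map <- new_contact_map(full, binning, mask = cm$mask)
    map
  })
}

#' Write a contact map in the sparse triplet dialect
#'
#' Upper-triangle (including diagonal) nonzero entries as
#' `start1 <tab> start2 <tab> count`, readable by [read_contact_map()].
#'
#' @param M A contact map.
#' @param path Output path.
#' @export
write_contact_map <- function(M, path) {
  stopifnot(inherits(M, "contact_map"))
  starts <- bin_starts(M$binning)
  idx <- which(upper.tri(M$counts, diag = TRUE) & M$counts != 0, arr.ind = TRUE)
  df <- data.frame(
    s1 = format(starts[idx[, 1L]], scientific = FALSE, trim = TRUE),
    s2 = format(starts[idx[, 2L]], scientific = FALSE, trim = TRUE),
    count = M$counts[idx]
  )
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(NULL)
}

#' Nested two-level synthetic benchmark
#'
#' Builds a hierarchical ground truth — contiguous sub-domains nested inside
#' contiguous super-domains — and an empirical correlation matrix sampled
#' from the two-level group model, for multi-scale sweep benchmarks.
#' Sub-domain strengths are drawn uniformly from `g_range` so that the
#' lambda at which each sub-domain merges into its super-domain varies,
#' spreading the coarsening transition over a range of penalties.
#'
#' @param N Number of bins (default 500).
#' @param n_super Number of super-domains (default 5).
#' @param sub_mean_size Mean sub-domain size in bins (default 12).
#' @param g_range Range of per-sub-domain strengths (default `c(1, 4)`).
#' @param h Per-super-domain secondary strength (default 1).
#' @param n_samples Samples for the empirical correlation (default 500).
#' @param seed Optional integer seed.
#' @return List with `s_sub`, `s_super` ([domain_solution()]s), `g`, and
#'   `C_hat` (a [correlation_matrix()]).
#' @export
nested_benchmark <- function(N = 500L, n_super = 5L, sub_mean_size = 12L,
                             g_range = c(1, 4), h = 1, n_samples = 500L,
                             seed = NULL) {
  .with_seed(seed, {
    super_size <- N / n_super
    stopifnot(super_size == round(super_size))
    super_lab <- rep(seq_len(n_super), each = super_size)
    # sub-domain boundaries: Bernoulli within supers, plus every super start
    newdom <- stats::runif(N) < 1 / sub_mean_size
    newdom[seq.int(1L, N, by = super_size)] <- TRUE
    sub_lab <- cumsum(newdom)
    s_sub <- domain_solution(sub_lab)
    s_super <- domain_solution(super_lab)
    g <- stats::runif(max(sub_lab), g_range[1L], g_range[2L])
    sig <- sample_signals(s_sub, g = g, u = s_super, h = h,
                          n_samples = n_samples)
    list(s_sub = s_sub, s_super = s_super, g = g, h = h, C_hat = sig$C_hat)
  })
}
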