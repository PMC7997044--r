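#' Similarity of two partitions via their co-membership matrices
#'
#' Represents each partition by its binary co-membership matrix
#' `B_ij = [s_i == s_j]` and returns the Pearson correlation of the two
#' matrices over all distinct valid pairs (`i != j`).  Invariant under label
#' permutation of either partition.
#'
#' @param s,s2 Two [domain_solution()]s on the same mask.
#' @return The correlation `rho` in `[-1, 1]`, or `NA` (with a warning) if
#'   either co-membership matrix has zero variance (e.g. a single domain).
#' @export
binary_similarity <- function(s, s2) {
  stopifnot(inherits(s, "domain_solution"), inherits(s2, "domain_solution"))
  if (!identical(s$mask, s2$mask)) stop("solutions are on different masks")
  a <- .valid_labels(s)
  b <- .valid_labels(s2)
  off <- upper.tri(diag(length(a)))
  B1 <- outer(a, a, "==")[off]
  B2 <- outer(b, b, "==")[off]
  if (stats::var(B1) == 0 || stats::var(B2) == 0) {
    warning("zero-variance co-membership matrix; similarity undefined")
    return(NA_real_)
  }
  stats::cor(B1, B2)
}

#' Normalized mutual information between a matrix and a partition
#'
#' Discretizes the symmetric data matrix `A` (e.g. `log10` of the balanced
#' contact map, or the O/E Pearson correlation matrix) into `n_bins`
#' equal-width bins over its range, pairs each off-diagonal element with the
#' binary co-membership indicator of the partition, and returns
#' `I(A;B) / sqrt(H(A) * H(B))` computed from the joint distribution over
#' distinct valid pairs.  Lies in `[0, 1]` and is independent of the
#' logarithm base.
#'
#' @param A Symmetric numeric matrix (full `N x N`, masked bins ignored).
#' @param s A [domain_solution()].
#' @param n_bins Number of discretization bins for `A` (default 100).
#' @return The nMI, or `NA` if `A` is constant over the used pairs.
#' @export
nmi <- function(A, s, n_bins = 100L) {
  stopifnot(is.matrix(A), inherits(s, "domain_solution"))
  v <- which(s$mask)
  lab <- .valid_labels(s)
  off <- upper.tri(diag(length(v)))
  a <- A[v, v, drop = FALSE][off]
  b <- outer(lab, lab, "==")[off]
  keep <- is.finite(a)
  a <- a[keep]; b <- b[keep]
  rng <- range(a)
  if (diff(rng) == 0) {
    warning("constant data matrix; nMI undefined")
    return(NA_real_)
  }
  da <- diff(rng) / n_bins
  ai <- pmin(floor((a - rng[1L]) / da) + 1L, n_bins)
  tab <- table(factor(ai, levels = seq_len(n_bins)), factor(b, levels = c(FALSE, TRUE)))
  p <- tab / sum(tab)
  pa <- rowSums(p); pb <- colSums(p)
  ent <- function(q) { q <- q[q > 0]; -sum(q * log(q)) }
  pij <- p[p > 0]
  pprod <- outer(pa, pb)[p > 0]
  I <- sum(pij * log(pij / pprod))
  I / sqrt(ent(pa) * ent(pb))
}

#' Nestedness of one partition inside another
#'
#' Measures how completely the (smaller) domains of `s_small` sit inside the
#' (larger) domains of `s_large`.  For each domain `k` of `s_small`, the raw
#' score `h1 = max_k' v_{k,k'} / n_k` is the best fractional overlap with a
#' single domain of `s_large`; the chance level `h1_bar` is estimated by
#' drawing `n_k` random sites (without replacement) from `s_large` over
#' `n_null` trials; the normalized score is
#' `h1_hat = (h1 - h1_bar) / (1 - h1_bar)` (0 = chance, 1 = perfectly
#' nested).  The overall score is the size-weighted mean
#' `h = sum_k h1_hat_k * n_k / N`, taken over the domains whose chance level
#' is below 1 (singleton domains are always perfectly nested by chance and
#' carry no information).
#'
#' @param s_small,s_large Two [domain_solution()]s on the same mask.
#' @param n_null Number of null draws per domain (default 100).
#' @param seed Optional integer seed for the null draws.
#' @return An object of class `"nestedness"`: list with `h` and a
#'   `per_domain` data.frame (`domain`, `n`, `h1`, `h1_bar`, `h1_hat`).
#' @export
nestedness <- function(s_small, s_large, n_null = 100L, seed = NULL) {
  if (!identical(s_small$mask, s_large$mask))
    stop("solutions are on different masks")
  a <- .valid_labels(s_small)
  b <- .valid_labels(s_large)
  N <- length(a)
  .with_seed(seed, {
    Ks <- max(a)
    per <- lapply(seq_len(Ks), function(k) {
      idx <- which(a == k)
      nk <- length(idx)
      h1 <- max(tabulate(b[idx], nbins = max(b))) / nk
      nulls <- vapply(seq_len(n_null), function(t) {
        draw <- b[sample.int(N, nk)]
        max(tabulate(draw, nbins = max(b))) / nk
      }, 0)
      h1_bar <- mean(nulls)
      h1_hat <- if (1 - h1_bar < 1e-12) NA_real_ else (h1 - h1_bar) / (1 - h1_bar)
      data.frame(domain = k, n = nk, h1 = h1, h1_bar = h1_bar, h1_hat = h1_hat)
    })
    per <- do.call(rbind, per)
    if (anyNA(per$h1_hat))
      warning("chance level 1 for some domains (singletons, or s_large a ",
              "single domain); they carry no information and are dropped")
    ok <- !is.na(per$h1_hat)
    # weight over the scored mass so degenerate domains do not dilute h
    h <- if (any(ok)) sum(per$h1_hat[ok] * per$n[ok]) / sum(per$n[ok])
         else NA_real_
    structure(list(h = h, per_domain = per, n_null = n_null),
              class = "nestedness")
  })
}

#' @export
print.nestedness <- function(x, ...) {
  cat(sprintf("<nestedness> h = %.4f over %d domains (%d null draws/domain)\n",
              x$h, nrow(x$per_domain), x$n_null))
  invisible(x)
}

#' Domain-size statistics
#'
#' Mean domain size (in bins and, when a binning is available, in Mb) and the
#' index of dispersion `D = var(n) / mean(n)` of the sizes (computed on sizes
#' in Mb by default, so that the crossover `D ~ 1` is on the genomic scale;
#' population variance).
#'
#' @param s A [domain_solution()].
#' @param binning Optional [genomic_binning()] for bp conversion.
#' @param units Units for the dispersion: `"Mb"` (default, requires a
#'   binning) or `"bins"`.
#' @return List with `sizes` (bins), `mean_size_bins`, `mean_size_Mb`,
#'   `dispersion`.
#' @export
size_stats <- function(s, binning = NULL, units = c("Mb", "bins")) {
  units <- match.arg(units)
  sizes <- tabulate(.valid_labels(s))
  mb <- if (!is.null(binning)) sizes * binning$bin_size / 1e6 else NULL
  x <- if (units == "Mb") {
    if (is.null(mb)) stop("units = 'Mb' requires a binning")
    mb
  } else sizes
  m <- mean(x)
  D <- mean((x - m)^2) / m
  list(sizes = sizes, mean_size_bins = mean(sizes),
       mean_size_Mb = if (is.null(mb)) NA_real_ else mean(mb),
       dispersion = D)
}

#' Cross-correlation between a signal track and domain boundaries
#'
#' Builds the boundary indicator `psi` (1 on the first bin of every maximal
#' contiguous run of a domain label, including the leftmost valid bin) and
#' evaluates the displacement-dependent normalized overlap
#' `chi(d) = <dphi(i + d) psi(i)>_i / <psi>`, where `dphi` is the track minus
#' its mean over valid bins.  A correlation length is estimated by an
#' unweighted least-squares fit of `log |chi|` to `log A - |d| / ell` over
#' the positive values at `d in [0, d_max]`.
#'
#' @param track A [signal_track()] on the same binning as `s`.
#' @param s A [domain_solution()].
#' @param d_max Maximum displacement in bins (default 40).
#' @return An object of class `"boundary_correlation"`: list with `d`
#'   (displacements `-d_max .. d_max`), `chi`, `psi`,
#'   `correlation_length_bins`, `correlation_length_bp`.
#' @export
boundary_correlation <- function(track, s, d_max = 40L) {
  stopifnot(inherits(track, "signal_track"), inherits(s, "domain_solution"))
  if (length(track$values) != length(s$labels))
    stop("track and solution have different lengths")
  v <- which(s$mask)
  lab <- .valid_labels(s)
  phi <- track$values[v]
  runs <- rle(lab)
  nb <- length(phi)
  psi <- numeric(nb)
  psi[cumsum(runs$lengths) - runs$lengths + 1L] <- 1
  if (sum(psi) <= 1 && length(unique(lab)) == 1L)
    stop("single-domain solution has no boundaries")
  dphi <- phi - mean(phi, na.rm = TRUE)
  dphi[is.na(dphi)] <- 0
  ds <- (-d_max):d_max
  chi <- vapply(ds, function(d) {
    i <- seq_len(nb)
    j <- i + d
    ok <- j >= 1L & j <= nb
    mean(dphi[j[ok]] * psi[i[ok]]) / mean(psi)
  }, 0)
  # exponential decay fit on |chi|, d >= 0
  dd <- ds[ds >= 0]
  cc <- abs(chi[ds >= 0])
  pos <- cc > 0
  ell <- NA_real_
  if (sum(pos) >= 2L) {
    fit <- stats::lm(log(cc[pos]) ~ dd[pos])
    slope <- stats::coef(fit)[[2L]]
    if (is.finite(slope) && slope < 0) ell <- -1 / slope
  }
  structure(list(d = ds, chi = chi, psi = psi,
                 correlation_length_bins = ell,
                 correlation_length_bp = if (is.na(ell)) NA_real_ else
                   ell * track$binning$bin_size),
            class = "boundary_correlation")
}

#' @export
print.boundary_correlation <- function(x, ...) {
  cat(sprintf("<boundary correlation> chi(0) = %.4f, correlation length = %s bins\n",
              x$chi[x$d == 0], format(x$correlation_length_bins, digits = 4)))
  invisible(x)
}

#' Assign A/B identities to the two largest domains
#'
#' Computes, for each of the two largest domains, the mean balanced contact
#' as a function of genomic distance among its members; the domain with the
#' higher mean contact at short range (distances `1 .. short_range` bins) is
#' the locally more compact one and is labeled B, the other A.
#'
#' @param s A [domain_solution()] with at least two domains.
#' @param M A balanced contact map on the same bins.
#' @param short_range Number of short-range distances to average (default
#'   10 bins; distance 0 excluded).
#' @return List with `A` and `B` (domain labels), and `profiles` (a
#'   `data.frame` with columns `d`, and mean contacts for each of the two
#'   domains).
#' @export
assign_AB <- function(s, M, short_range = 10L) {
  stopifnot(inherits(M, "balanced_contact_map"))
  lab <- .valid_labels(s)
  v <- which(s$mask)
  sizes <- tabulate(lab)
  if (length(sizes) < 2L) stop("need at least two domains for A/B assignment")
  top2 <- order(sizes, decreasing = TRUE)[1:2]
  top2 <- sort(top2)  # deterministic order for the tie path
  prof <- function(k) {
    idx <- v[lab == k]
    sub <- M$counts[idx, idx, drop = FALSE]
    d <- abs(outer(idx, idx, "-"))
    sel <- d > 0
    tapply(sub[sel], d[sel], mean)
  }
  p1 <- prof(top2[1L]); p2 <- prof(top2[2L])
  short <- function(p) {
    dd <- as.integer(names(p))
    mean(p[dd >= 1 & dd <= short_range])
  }
  m1 <- short(p1); m2 <- short(p2)
  if (isTRUE(all.equal(m1, m2))) {
    warning("identical short-range profiles; tie broken by domain label order")
    B <- top2[1L]; A <- top2[2L]
  } else if (m1 > m2) {
    B <- top2[1L]; A <- top2[2L]
  } else {
    B <- top2[2L]; A <- top2[1L]
  }
  dmax <- max(as.integer(names(p1)), as.integer(names(p2)))
  dgrid <- seq_len(dmax)
  profiles <- data.frame(
    d = dgrid,
    domain1 = p1[as.character(dgrid)],
    domain2 = p2[as.character(dgrid)]
  )
  names(profiles)[2:3] <- paste0("domain", top2)
  list(A = A, B = B, profiles = profiles,
       short_range_means = stats::setNames(c(m1, m2), paste0("domain", top2)))
}

#' Correlation of a compartment split with a genomic signal
#'
#' Builds the signed indicator vectors `q^(A)` (+1 on compartment A bins, -1
#' elsewhere) and `q^(B)` and returns the normalized projections
#' `c_A = (q^(A) . h) / (|q^(A)| |h|)` and likewise `c_B`, where `h` is the
#' per-bin track.  When the solution is exactly two domains covering all
#' bins, `c_B = -c_A`.
#'
#' @param s A [domain_solution()].
#' @param A_label,B_label Domain labels of the A and B compartments.
#' @param track A [signal_track()].
#' @return Named numeric vector `c(c_A = ..., c_B = ...)`, `NA` if the track
#'   has zero norm.
#' @export
compartment_track_correlation <- function(s, A_label, B_label, track) {
  stopifnot(A_label != B_label)
  lab <- .valid_labels(s)
  h <- track$values[s$mask]
  h[is.na(h)] <- 0
  if (sqrt(sum(h^2)) == 0) {
    warning("zero-norm track")
    return(c(c_A = NA_real_, c_B = NA_real_))
  }
  qa <- ifelse(lab == A_label, 1, -1)
  qb <- ifelse(lab == B_label, 1, -1)
  proj <- function(q) sum(q * h) / (sqrt(sum(q^2)) * sqrt(sum(h^2)))
  c(c_A = proj(qa), c_B = proj(qb))
}
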