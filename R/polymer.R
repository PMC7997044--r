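#' Contact probability of a harmonically restrained segment pair
#'
#' For a pair of polymer segments whose distance follows the radial Gaussian
#' density with stiffness `gamma`, the probability that the distance falls
#' below the capture radius `r_c` has the closed form
#' `erf(sqrt(gamma) * r_c) - 2 * r_c * sqrt(gamma / pi) * exp(-gamma * r_c^2)`.
#' It increases monotonically from 0 at `gamma = 0` to 1 as `gamma -> Inf`.
#'
#' @param gamma Non-negative stiffness (vectorized), in units of `r_c^-2`.
#' @param r_c Capture radius (> 0, dimensionless; default 1).
#'
#' @return Contact probabilities in `[0, 1]`.
#' @export
contact_probability <- function(gamma, r_c = 1) {
  if (any(gamma < 0, na.rm = TRUE)) stop("'gamma' must be non-negative")
  if (r_c <= 0) stop("'r_c' must be positive")
  x <- sqrt(gamma) * r_c
  erf <- 2 * stats::pnorm(x * sqrt(2)) - 1
  p <- erf - (2 * r_c) * sqrt(gamma / pi) * exp(-gamma * r_c^2)
  pmin(pmax(p, 0), 1)
}

# derivative dp/dgamma = 2 r_c^3 sqrt(gamma) exp(-gamma r_c^2) / sqrt(pi)
.dp_dgamma <- function(gamma, r_c = 1) {
  2 * r_c^3 * sqrt(gamma) * exp(-gamma * r_c^2) / sqrt(pi)
}

#' Invert the contact-probability map
#'
#' Solves `contact_probability(gamma, r_c) = p` for `gamma` on the monotone
#' branch.  Vectorized over `p` via a precomputed log-spaced lookup grid with
#' Newton polishing.  `p = 1` entries (saturated contacts) are assigned the
#' finite cap `invert_contact_probability(1 - 1e-6)` and flagged via the
#' `"saturated"` attribute.
#'
#' @param p Probabilities in `[0, 1]` (vectorized).
#' @param r_c Capture radius.
#' @param tol Absolute tolerance on the recovered probability
#'   (default `1e-10`).
#'
#' @return Stiffness values `gamma >= 0`, with attribute `"saturated"`
#'   (logical) marking `p = 1` entries.
#' @export
invert_contact_probability <- function(p, r_c = 1, tol = 1e-10) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("'p' must lie in [0, 1]")
  sat <- !is.na(p) & p >= 1
  p_eff <- ifelse(sat, 1 - 1e-6, p)
  # lookup grid in gamma*r_c^2 (dimensionless), monotone in p
  grid_g <- c(0, exp(seq(log(1e-9), log(60), length.out = 4096L)))
  grid_p <- contact_probability(grid_g, r_c = 1)
  u <- p_eff  # solve for z = gamma * r_c^2 at r_c = 1, rescale after
  z <- rep(NA_real_, length(u))
  ok <- !is.na(u)
  z[ok & u == 0] <- 0
  todo <- ok & u > 0
  if (any(todo)) {
    i <- findInterval(u[todo], grid_p, all.inside = TRUE)
    # linear interpolation start, then Newton on the closed form
    g0 <- grid_g[i] + (grid_g[i + 1L] - grid_g[i]) *
      (u[todo] - grid_p[i]) / pmax(grid_p[i + 1L] - grid_p[i], 1e-300)
    g0 <- pmax(g0, 1e-12)
    for (iter in 1:100) {
      f <- contact_probability(g0, 1) - u[todo]
      step <- f / pmax(.dp_dgamma(g0, 1), 1e-300)
      g0 <- pmax(g0 - step, g0 / 10)
      # converge to machine precision in gamma (relative), not just in p
      if (all(abs(f) <= tol) && all(abs(step) <= 1e-13 * g0)) break
    }
    z[todo] <- g0
  }
  gamma <- z / r_c^2
  dim(gamma) <- dim(p)
  dim(sat) <- dim(p)
  attr(gamma, "saturated") <- sat
  gamma
}

#' Convert balanced contacts to contact probabilities
#'
#' Rescales the balanced Hi-C matrix so that the average nearest-neighbour
#' contact probability equals `p1bar`, then clips at 1:
#' `p_ij = min(1, (p1bar / mu) * M_ij)` with `mu` the mean of the valid
#' nearest-neighbour entries.
#'
#' @param M A balanced contact map.
#' @param p1bar Target average nearest-neighbour contact probability
#'   (default 0.9).
#'
#' @return A list of class `"contact_probability_matrix"` with elements `p`
#'   (matrix), `p1bar`, `mu`, `saturated_fraction`, `binning`, `mask`.
#' @export
contacts_to_probability <- function(M, p1bar = 0.9) {
  stopifnot(inherits(M, "balanced_contact_map"), p1bar > 0, p1bar <= 1)
  v <- which(M$mask)
  nn <- cbind(v[-length(v)], v[-1L])
  nn <- nn[nn[, 2L] - nn[, 1L] == 1L, , drop = FALSE]  # adjacent valid pairs
  if (nrow(nn) == 0L) stop("no valid nearest-neighbour pairs")
  mu <- mean(M$counts[nn])
  if (!is.finite(mu) || mu <= 0) stop("mean nearest-neighbour signal is zero")
  p <- (p1bar / mu) * M$counts
  over <- !is.na(p) & p > 1
  # saturation is only meaningful off the diagonal (self-contact never enters
  # the correlation construction)
  ov <- over[M$mask, M$mask, drop = FALSE]
  satfrac <- sum(ov[row(ov) != col(ov)]) / max(1, sum(M$mask)^2 - sum(M$mask))
  if (satfrac > 0.1)
    warning(sprintf("%.1f%% of contact probabilities saturated at 1; consider a smaller p1bar",
                    100 * satfrac))
  p[over] <- 1
  structure(list(p = p, p1bar = p1bar, mu = mu, saturated_fraction = satfrac,
                 binning = M$binning, mask = M$mask),
            class = "contact_probability_matrix")
}

#' Map a stiffness matrix to a correlation matrix
#'
#' Sets the uniform variance scale `sigma_c` to the median of `1/(4*gamma)`
#' over valid, unsaturated off-diagonal entries (a choice that balances the
#' fractions of positive and negative correlations and cancels the `r_c`
#' scale), then applies `C_ij = 1 - 1/(4 * sigma_c * gamma_ij)`, clamping
#' off-diagonal entries into `[-1, 1 - 1e-6]`.
#'
#' @param gamma Symmetric non-negative stiffness matrix.
#' @param mask Logical vector of valid bins.
#' @param saturated Optional logical matrix flagging entries whose stiffness
#'   is a saturation cap (excluded from the `sigma_c` median).
#' @param binning Optional [genomic_binning()].
#'
#' @return A [correlation_matrix()] carrying `sigma_c`.
#' @export
gamma_to_correlation <- function(gamma, mask = NULL, saturated = NULL,
                                 binning = NULL) {
  stopifnot(is.matrix(gamma), nrow(gamma) == ncol(gamma))
  N <- nrow(gamma)
  if (is.null(mask)) mask <- rep(TRUE, N)
  if (is.null(saturated)) saturated <- matrix(FALSE, N, N)
  v <- which(mask)
  offdiag <- outer(v, v, "!=")
  g_off <- gamma[v, v, drop = FALSE][offdiag & !saturated[v, v, drop = FALSE]]
  g_off <- g_off[is.finite(g_off) & g_off > 0]
  if (length(g_off) == 0L) stop("degenerate contact map: no positive stiffness")
  sigma_c <- stats::median(1 / (4 * g_off))
  C <- 1 - 1 / (4 * sigma_c * gamma)   # gamma = 0 gives -Inf, clamped below
  C <- pmin(pmax(C, -1), 1 - 1e-6)
  diag(C) <- 1
  C[!mask, ] <- NA_real_
  C[, !mask] <- NA_real_
  diag(C) <- 1
  correlation_matrix(C, binning = binning, mask = mask, sigma_c = sigma_c)
}

#' Hi-C preprocessing chain: raw counts to polymer correlation matrix
#'
#' Composes [mask_low_coverage()], [kr_normalize()],
#' [contacts_to_probability()], [invert_contact_probability()] (elementwise)
#' and [gamma_to_correlation()].  The resulting correlation matrix is
#' independent of `r_c`, which only rescales the stiffnesses.
#'
#' @param M_raw A raw contact map.
#' @param p1bar Average nearest-neighbour contact probability anchor
#'   (default 0.9).
#' @param r_c Capture radius (default 1; the output is invariant to it).
#' @param min_nonzero_fraction Low-coverage masking threshold.
#' @param kr_tol,kr_max_iter Knight-Ruiz balancing controls.
#'
#' @return A [correlation_matrix()].
#' @export
preprocess_hic <- function(M_raw, p1bar = 0.9, r_c = 1,
                           min_nonzero_fraction = 0, kr_tol = 1e-6,
                           kr_max_iter = 100L) {
  stopifnot(inherits(M_raw, "contact_map"))
  M <- mask_low_coverage(M_raw, min_nonzero_fraction)
  Mb <- kr_normalize(M, tol = kr_tol, max_iter = kr_max_iter)
  P <- contacts_to_probability(Mb, p1bar = p1bar)
  v <- which(P$mask)
  N <- nrow(P$p)
  gamma <- matrix(NA_real_, N, N)
  sat <- matrix(FALSE, N, N)
  pv <- P$p[v, v, drop = FALSE]
  gv <- invert_contact_probability(pv, r_c = r_c)
  gamma[v, v] <- gv
  sat[v, v] <- attr(gv, "saturated")
  gamma_to_correlation(gamma, mask = P$mask, saturated = sat,
                       binning = P$binning)
}

#' Exclude a near-diagonal band from a correlation matrix
#'
#' Marks pairs with `|i - j| * bin_size <= band_width` (and `i != j`) as
#' carrying no evidence; used before secondary (compartment) inference to
#' remove the short-range signal of local domains (e.g. a 2-Mb band, the
#' meta-TAD scale).
#'
#' @param cm A [correlation_matrix()] with a binning (or give `bin_size`).
#' @param band_width Band half-width in bp.
#' @param bin_size Bin size in bp, if `cm` carries no binning.
#'
#' @return The correlation matrix with the band recorded in `band_bins`.
#' @export
band_mask <- function(cm, band_width, bin_size = NULL) {
  stopifnot(inherits(cm, "correlation_matrix"), band_width >= 0)
  if (is.null(bin_size)) {
    if (is.null(cm$binning)) stop("supply 'bin_size' or a binning")
    bin_size <- cm$binning$bin_size
  }
  N <- nrow(cm$C)
  if (band_width >= as.numeric(N) * bin_size)
    stop("band of ", band_width, " bp covers the entire matrix")
  cm$band_bins <- as.integer(floor(band_width / bin_size))
  cm
}
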