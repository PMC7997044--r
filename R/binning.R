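#' Genomic binning of a chromosome
#'
#' Describes how a chromosome (or a region of one) is tiled into fixed-width
#' bins.  Bin `i` (1-based in R) covers the 0-based half-open genomic interval
#' `[start_offset + (i-1)*bin_size, start_offset + i*bin_size)`.
#'
#' @param chromosome Chromosome name, e.g. `"chr10"`.
#' @param bin_size Bin width in base pairs (> 0).
#' @param n_bins Number of bins (> 0).
#' @param start_offset Genomic start of the first bin in bp (default 0).
#'
#' @return An object of class `"genomic_binning"`.
#' @export
genomic_binning <- function(chromosome, bin_size, n_bins, start_offset = 0) {
  stopifnot(is.character(chromosome), length(chromosome) == 1L)
  bin_size <- as.integer(bin_size)
  n_bins <- as.integer(n_bins)
  start_offset <- as.numeric(start_offset)
  if (is.na(bin_size) || bin_size <= 0L) stop("'bin_size' must be a positive integer")
  if (is.na(n_bins) || n_bins <= 0L) stop("'n_bins' must be a positive integer")
  structure(
    list(chromosome = chromosome, bin_size = bin_size, n_bins = n_bins,
         start_offset = start_offset),
    class = "genomic_binning"
  )
}

#' @export
print.genomic_binning <- function(x, ...) {
  cat(sprintf("<genomic_binning> %s: %d bins of %s bp starting at %s\n",
              x$chromosome, x$n_bins, format(x$bin_size, big.mark = ","),
              format(x$start_offset, big.mark = ",")))
  invisible(x)
}

# bin start coordinates (bp, 0-based) for bins 1..n_bins
bin_starts <- function(binning) {
  binning$start_offset + (seq_len(binning$n_bins) - 1) * as.numeric(binning$bin_size)
}

new_contact_map <- function(counts, binning, mask, balanced = FALSE,
                            balance_vector = NULL) {
  stopifnot(is.matrix(counts), nrow(counts) == ncol(counts))
  if (is.null(mask)) mask <- rep(TRUE, nrow(counts))
  stopifnot(length(mask) == nrow(counts))
  structure(
    list(counts = counts, binning = binning, mask = mask,
         balance_vector = balance_vector),
    class = c(if (balanced) "balanced_contact_map" else "raw_contact_map",
              "contact_map")
  )
}

#' @export
print.contact_map <- function(x, ...) {
  kind <- if (inherits(x, "balanced_contact_map")) "balanced" else "raw"
  cat(sprintf("<%s contact map> %d x %d bins (%d valid), %s, %s-bp bins\n",
              kind, nrow(x$counts), ncol(x$counts), sum(x$mask),
              x$binning$chromosome, format(x$binning$bin_size, big.mark = ",")))
  invisible(x)
}

#' Construct a correlation-matrix object
#'
#' Container for a pairwise correlation matrix over genomic bins: unit
#' diagonal, symmetric, off-diagonal entries in `[-1, 1]`, with an optional
#' validity mask and an optional excluded diagonal band.  Used both for the
#' polymer-model correlation matrix and for the Pearson correlation of the
#' observed/expected contact matrix.
#'
#' @param C Symmetric numeric matrix with unit diagonal.
#' @param binning Optional [genomic_binning()].
#' @param mask Logical vector of valid bins (default all valid).
#' @param sigma_c Uniform variance scale used to build `C`, if applicable.
#' @param band_bins Number of excluded near-diagonal distances: pairs with
#'   `|i - j| <= band_bins` (and `i != j`) carry no evidence in likelihoods.
#'   0 means no band.
#'
#' @return An object of class `"correlation_matrix"`.
#' @export
correlation_matrix <- function(C, binning = NULL, mask = NULL, sigma_c = NA_real_,
                               band_bins = 0L) {
  stopifnot(is.matrix(C), nrow(C) == ncol(C))
  if (is.null(mask)) mask <- rep(TRUE, nrow(C))
  stopifnot(length(mask) == nrow(C))
  v <- which(mask)
  sub <- C[v, v, drop = FALSE]
  if (length(v) && max(abs(sub - t(sub)), na.rm = TRUE) > 1e-8)
    stop("correlation matrix is not symmetric over valid bins")
  if (length(v) && any(abs(diag(sub) - 1) > 1e-8, na.rm = TRUE))
    stop("correlation matrix must have unit diagonal")
  off <- sub[row(sub) != col(sub)]
  if (length(off) && (min(off, na.rm = TRUE) < -1 - 1e-8 ||
                      max(off, na.rm = TRUE) > 1 + 1e-8))
    stop("off-diagonal correlations must lie in [-1, 1]")
  structure(
    list(C = C, binning = binning, mask = mask, sigma_c = sigma_c,
         band_bins = as.integer(band_bins)),
    class = "correlation_matrix"
  )
}

#' @export
print.correlation_matrix <- function(x, ...) {
  cat(sprintf("<correlation matrix> %d x %d bins (%d valid)", nrow(x$C),
              ncol(x$C), sum(x$mask)))
  if (!is.na(x$sigma_c)) cat(sprintf(", sigma_c = %.4g", x$sigma_c))
  if (x$band_bins > 0L) cat(sprintf(", band of %d bins excluded", x$band_bins))
  cat("\n")
  invisible(x)
}

# The evidence matrix actually used in likelihoods: valid-bin submatrix with
# band-excluded off-diagonal entries zeroed (they carry no evidence; the
# diagonal always contributes 1).
evidence_matrix <- function(cm) {
  stopifnot(inherits(cm, "correlation_matrix"))
  v <- which(cm$mask)
  A <- cm$C[v, v, drop = FALSE]
  if (cm$band_bins > 0L) {
    d <- abs(outer(v, v, "-"))  # band distances are in original bin units
    A[d <= cm$band_bins & d > 0L] <- 0
  }
  diag(A) <- 1
  A
}

#' Per-bin genomic signal track
#'
#' @param values Numeric vector of per-bin signal, `NA` for missing bins.
#' @param binning A [genomic_binning()]; `length(values)` must equal
#'   `binning$n_bins`.
#' @param name Track name.
#'
#' @return An object of class `"signal_track"`.
#' @export
signal_track <- function(values, binning, name = "signal") {
  stopifnot(is.numeric(values))
  if (length(values) != binning$n_bins)
    stop("track length does not match binning$n_bins")
  structure(list(values = as.numeric(values), binning = binning, name = name),
            class = "signal_track")
}

#' @export
print.signal_track <- function(x, ...) {
  cat(sprintf("<signal track> '%s': %d bins, %d missing\n", x$name,
              length(x$values), sum(is.na(x$values))))
  invisible(x)
}
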