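#' Read an intra-chromosomal Hi-C contact matrix
#'
#' Reads either the sparse triplet dialect used for the GEO GSE63525
#' distribution (`start1 <tab> start2 <tab> count`, coordinates are bin-start
#' base pairs) or a dense whitespace-separated numeric matrix.  The format is
#' auto-detected from the number of tokens on the first data line (3 tokens =
#' triplet).  Triplet records are mirrored across the diagonal; unseen pairs
#' are 0.
#'
#' @param path Path to the matrix file.
#' @param bin_size Bin width in bp.
#' @param chromosome Chromosome name recorded in the binning metadata.
#' @param n_bins Number of bins; if `NULL`, inferred from the largest
#'   coordinate (triplet input) or the matrix dimension (dense input).
#' @param start_offset Genomic coordinate of the first bin (bp, default 0).
#'
#' @return A raw contact map (class `"raw_contact_map"`).
#' @export
read_contact_map <- function(path, bin_size, chromosome = "chr?",
                             n_bins = NULL, start_offset = 0) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("no records in '", path, "'")
  first <- strsplit(trimws(lines[[1L]]), "[ \t]+")[[1L]]
  if (length(first) == 3L) {
    counts <- .read_triplets(lines, bin_size, n_bins, start_offset, path)
  } else {
    counts <- .read_dense(lines, path)
    if (!is.null(n_bins) && nrow(counts) != n_bins)
      stop("dense matrix has ", nrow(counts), " rows but n_bins = ", n_bins)
  }
  if (any(counts < 0)) stop("negative contact counts in '", path, "'")
  binning <- genomic_binning(chromosome, bin_size, nrow(counts), start_offset)
  new_contact_map(counts, binning, mask = NULL)
}

.read_triplets <- function(lines, bin_size, n_bins, start_offset, path) {
  toks <- strsplit(trimws(lines), "[ \t]+")
  bad <- which(lengths(toks) != 3L)
  if (length(bad))
    stop("line ", bad[1L], ": expected 3 fields, found ", lengths(toks)[bad[1L]])
  m <- matrix(suppressWarnings(as.numeric(unlist(toks))), ncol = 3L, byrow = TRUE)
  if (anyNA(m)) {
    bad <- which(apply(is.na(m), 1L, any))[1L]
    stop("line ", bad, ": non-numeric field")
  }
  pos <- m[, 1:2, drop = FALSE] - start_offset
  off <- pos %% bin_size
  if (any(off != 0)) {
    bad <- which(rowSums(off != 0) > 0)[1L]
    stop("line ", bad, ": coordinate not a multiple of bin_size (", bin_size, ")")
  }
  idx <- pos / bin_size + 1  # 1-based bin indices
  if (is.null(n_bins)) n_bins <- max(idx)
  if (max(idx) > n_bins) stop("coordinate beyond n_bins in '", path, "'")
  counts <- matrix(0, n_bins, n_bins)
  counts[cbind(idx[, 1L], idx[, 2L])] <- m[, 3L]
  counts[cbind(idx[, 2L], idx[, 1L])] <- m[, 3L]
  counts
}

.read_dense <- function(lines, path) {
  toks <- strsplit(trimws(lines), "[ \t]+")
  n <- length(toks[[1L]])
  if (any(lengths(toks) != n)) stop("ragged dense matrix in '", path, "'")
  vals <- suppressWarnings(as.numeric(unlist(toks)))
  if (anyNA(vals)) stop("non-numeric field in dense matrix '", path, "'")
  counts <- matrix(vals, ncol = n, byrow = TRUE)
  if (nrow(counts) != n) stop("dense matrix in '", path, "' is not square")
  if (max(abs(counts - t(counts))) > 1e-9)
    stop("dense matrix in '", path, "' is not symmetric (tolerance 1e-9)")
  counts
}

#' Mask unusable (low-coverage) bins
#'
#' Marks bins whose row is entirely zero, or whose fraction of nonzero entries
#' falls below `min_nonzero_fraction`, as invalid.  Matrix values are left
#' untouched; downstream steps skip masked bins.
#'
#' @param M A raw contact map.
#' @param min_nonzero_fraction Minimum fraction of nonzero entries for a bin
#'   to be kept, in `[0, 1]`.
#'
#' @return The contact map with an updated mask.
#' @export
mask_low_coverage <- function(M, min_nonzero_fraction = 0) {
  stopifnot(inherits(M, "contact_map"),
            min_nonzero_fraction >= 0, min_nonzero_fraction <= 1)
  n <- nrow(M$counts)
  nz_frac <- rowSums(M$counts > 0) / n
  keep <- rowSums(M$counts) > 0 & nz_frac >= min_nonzero_fraction
  M$mask <- M$mask & keep
  if (!any(M$mask)) stop("no usable bins after masking")
  M
}

#' Knight-Ruiz balancing of a contact matrix
#'
#' Finds a positive vector `v` such that `v_i v_j (M_raw)_ij` has every valid
#' row (and column) summing to 1, using the Knight-Ruiz inner-outer Newton
#' iteration restricted to valid bins.
#'
#' @param M A raw contact map (use [mask_low_coverage()] first so empty bins
#'   are excluded).
#' @param tol Row-sum tolerance (default `1e-6`).
#' @param max_iter Maximum outer iterations.
#'
#' @return A balanced contact map carrying the balance vector (NA on masked
#'   bins).
#' @export
kr_normalize <- function(M, tol = 1e-6, max_iter = 100L) {
  stopifnot(inherits(M, "contact_map"))
  v_idx <- which(M$mask)
  A <- M$counts[v_idx, v_idx, drop = FALSE]
  if (any(rowSums(A) == 0))
    stop("zero-sum rows among valid bins; apply mask_low_coverage() first")
  if (!.is_connected(A > 0))
    stop("contact graph on valid bins is reducible (disconnected); ",
         "mask more bins before balancing")
  x <- .kr_vector(A, tol = tol, max_iter = max_iter)
  vals <- matrix(NA_real_, nrow(M$counts), ncol(M$counts))
  vals[v_idx, v_idx] <- A * tcrossprod(x)
  bv <- rep(NA_real_, nrow(M$counts))
  bv[v_idx] <- x
  out <- new_contact_map(vals, M$binning, M$mask, balanced = TRUE,
                         balance_vector = bv)
  out
}

# connectivity of an undirected graph given a logical adjacency matrix
.is_connected <- function(adj) {
  n <- nrow(adj)
  if (n <= 1L) return(TRUE)
  seen <- logical(n)
  queue <- 1L
  seen[1L] <- TRUE
  while (length(queue)) {
    i <- queue[[1L]]; queue <- queue[-1L]
    nb <- which(adj[i, ] & !seen)
    seen[nb] <- TRUE
    queue <- c(queue, nb)
  }
  all(seen)
}

# Knight-Ruiz algorithm (inner CG / outer inexact Newton) for
# diag(x) A diag(x) 1 = 1 on a symmetric non-negative irreducible A.
.kr_vector <- function(A, tol = 1e-6, max_iter = 100L) {
  n <- nrow(A)
  e <- rep(1, n)
  x <- e
  delta <- 0.1; Delta <- 3
  g <- 0.9; etamax <- 0.1
  eta <- etamax
  rt <- tol^2
  v <- x * as.vector(A %*% x)
  rk <- 1 - v
  rho_km1 <- sum(rk * rk)
  rout <- rho_km1; rold <- rout
  it <- 0L
  while (rout > rt) {
    it <- it + 1L
    if (it > max_iter)
      stop(sprintf("KR balancing did not converge in %d iterations (residual %.3g)",
                   max_iter, sqrt(rout)))
    k <- 0L
    y <- e
    innertol <- max(eta^2 * rout, rt)
    rho_km1 <- sum(rk * rk)
    Z <- p <- NULL
    while (rho_km1 > innertol) {   # inner CG for the Newton step
      k <- k + 1L
      if (k == 1L) {
        Z <- rk / v
        p <- Z
        rho_km1 <- sum(rk * Z)
      }
      w <- x * as.vector(A %*% (x * p)) + v * p
      alpha <- rho_km1 / sum(p * w)
      ap <- alpha * p
      ynew <- y + ap
      if (min(ynew) <= delta) {
        if (delta == 0) break
        ind <- ap < 0
        gamma <- min((delta - y[ind]) / ap[ind])
        y <- y + gamma * ap
        break
      }
      if (max(ynew) >= Delta) {
        ind <- ynew > Delta
        gamma <- min((Delta - y[ind]) / ap[ind])
        y <- y + gamma * ap
        break
      }
      y <- ynew
      rk <- rk - alpha * w
      rho_km2 <- rho_km1
      Z <- rk / v
      rho_km1 <- sum(rk * Z)
      p <- Z + (rho_km1 / rho_km2) * p
      if (k > 200L) break
    }
    x <- x * y
    v <- x * as.vector(A %*% x)
    rk <- 1 - v
    rho_km1 <- sum(rk * rk)
    rout <- rho_km1
    # adaptive forcing term
    rat <- rout / rold; rold <- rout
    res_norm <- sqrt(rout)
    eta_o <- eta; eta <- g * rat
    if (g * eta_o^2 > 0.1) eta <- max(eta, g * eta_o^2)
    eta <- max(min(eta, etamax), 0.5 * tol / res_norm)
  }
  x
}

#' Distance-dependent expected contact profile
#'
#' Averages the balanced contact values over all valid pairs at each genomic
#' distance `d = |i - j|`, optionally smoothing each distance's mean over a
#' window that grows proportionally with `d`.  Distances with no valid pair
#' carry the last finite value forward.
#'
#' @param M A balanced contact map.
#' @param smoothing `"proportional"` (default) averages the raw per-distance
#'   means over `[d - ceil(f*d), d + ceil(f*d)]`; `"none"` disables smoothing.
#' @param window_fraction Proportional window half-width fraction `f`
#'   (default 0.01).
#'
#' @return Numeric vector of length `N` giving the expected value at
#'   distances `0 .. N-1`.
#' @export
expected_profile <- function(M, smoothing = c("proportional", "none"),
                             window_fraction = 0.01) {
  smoothing <- match.arg(smoothing)
  stopifnot(inherits(M, "balanced_contact_map"))
  v <- which(M$mask)
  A <- M$counts[v, v, drop = FALSE]
  d <- abs(outer(v, v, "-"))
  N <- nrow(M$counts)
  raw <- rep(NA_real_, N)
  sums <- tapply(A, d, sum)
  cnts <- tapply(rep(1, length(A)), d, sum)
  dd <- as.integer(names(sums))
  raw[dd + 1L] <- sums / cnts
  # carry last finite value forward for distances with no valid pair
  for (i in seq_len(N)) if (is.na(raw[i]) && i > 1L) raw[i] <- raw[i - 1L]
  if (smoothing == "none") return(raw)
  out <- raw
  for (i in seq_len(N)) {
    d0 <- i - 1L
    w <- ceiling(window_fraction * d0)
    if (w == 0) next
    lo <- max(0L, d0 - w); hi <- min(N - 1L, d0 + w)
    out[i] <- mean(raw[(lo:hi) + 1L], na.rm = TRUE)
  }
  out
}

#' Pearson correlation matrix of the observed/expected map
#'
#' Divides the balanced contact matrix by the distance-dependent expected
#' profile and computes the Pearson correlation between the rows of the
#' resulting observed/expected (O/E) matrix over valid bins.  Rows with zero
#' variance are masked and their correlations set to `NA`.
#'
#' @param M A balanced contact map.
#' @param expected Expected profile from [expected_profile()]; computed if
#'   missing.
#'
#' @return A [correlation_matrix()] (the C_O/E).
#' @export
oe_pearson <- function(M, expected = NULL) {
  stopifnot(inherits(M, "balanced_contact_map"))
  if (is.null(expected)) expected <- expected_profile(M)
  v <- which(M$mask)
  A <- M$counts[v, v, drop = FALSE]
  d <- abs(outer(v, v, "-"))
  ev <- expected[d + 1L]
  if (any(!is.finite(ev) | ev <= 0))
    stop("expected profile must be strictly positive where used")
  OE <- A / matrix(ev, nrow(A), ncol(A))
  sds <- apply(OE, 1L, stats::sd)
  ok <- sds > 0
  N <- nrow(M$counts)
  C <- matrix(NA_real_, N, N)
  if (sum(ok) >= 2L)
    C[v[ok], v[ok]] <- stats::cor(t(OE[ok, , drop = FALSE]))
  diag(C) <- 1
  mask <- logical(N)
  mask[v[ok]] <- TRUE
  if (any(!ok))
    warning(sum(!ok), " zero-variance O/E rows masked")
  correlation_matrix(C, binning = M$binning, mask = mask)
}

#' Bin an interval signal track onto a genomic binning
#'
#' An interval fully inside one bin contributes its value to that bin; an
#' interval straddling several bins splits its value evenly across them.
#' Multiple contributions to one bin are averaged; bins receiving no signal
#' are 0.
#'
#' @param intervals `data.frame` with columns `start`, `end` (bp, 0-based
#'   half-open) and `value`.
#' @param binning A [genomic_binning()].
#' @param name Track name.
#'
#' @return A [signal_track()].
#' @export
bin_signal_track <- function(intervals, binning, name = "signal") {
  stopifnot(is.data.frame(intervals),
            all(c("start", "end", "value") %in% names(intervals)))
  n <- binning$n_bins
  lo <- binning$start_offset
  hi <- lo + as.numeric(n) * binning$bin_size
  sums <- numeric(n)
  cnts <- integer(n)
  for (r in seq_len(nrow(intervals))) {
    s <- intervals$start[r]; e <- intervals$end[r]; val <- intervals$value[r]
    if (e <= lo || s >= hi) {
      warning("interval [", s, ",", e, ") outside binning range; skipped")
      next
    }
    if (s < lo || e > hi) {
      warning("interval [", s, ",", e, ") clipped to binning range")
      s <- max(s, lo); e <- min(e, hi)
    }
    b1 <- floor((s - lo) / binning$bin_size) + 1L
    b2 <- min(floor((e - lo - 1e-9) / binning$bin_size) + 1L, n)
    bins <- b1:b2
    share <- val / length(bins)
    sums[bins] <- sums[bins] + share
    cnts[bins] <- cnts[bins] + 1L
  }
  vals <- ifelse(cnts > 0L, sums / cnts, 0)
  signal_track(vals, binning, name = name)
}

#' Write a domain solution as a BED file
#'
#' Emits 0-based half-open records `chrom start end name`, one per maximal
#' contiguous run of a domain label; a non-local domain therefore produces
#' several records sharing a name.  Masked bins are written with name `"."`.
#'
#' @param s A domain solution (see [domain_solution()]).
#' @param binning A [genomic_binning()].
#' @param path Output file path.
#' @export
write_domains <- function(s, binning, path) {
  stopifnot(inherits(s, "domain_solution"))
  lab <- ifelse(s$mask, as.character(s$labels), ".")
  n <- length(lab)
  stopifnot(n == binning$n_bins)
  runs <- rle(lab)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  bp0 <- binning$start_offset + (starts - 1L) * as.numeric(binning$bin_size)
  bp1 <- binning$start_offset + ends * as.numeric(binning$bin_size)
  df <- data.frame(chrom = binning$chromosome,
                   start = format(bp0, scientific = FALSE, trim = TRUE),
                   end = format(bp1, scientific = FALSE, trim = TRUE),
                   name = runs$values)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(NULL)
}

#' Read a domain solution from a BED file written by [write_domains()]
#'
#' @param path BED file path.
#' @param binning The [genomic_binning()] the file was written against.
#' @return A [domain_solution()].
#' @export
read_domains <- function(path, binning) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          col.names = c("chrom", "start", "end", "name"),
                          colClasses = c("character", "numeric", "numeric",
                                         "character"))
  labels <- rep(NA_integer_, binning$n_bins)
  mask <- rep(FALSE, binning$n_bins)
  for (r in seq_len(nrow(df))) {
    b1 <- (df$start[r] - binning$start_offset) / binning$bin_size + 1L
    b2 <- (df$end[r] - binning$start_offset) / binning$bin_size
    if (df$name[r] == ".") next
    labels[b1:b2] <- as.integer(df$name[r])
    mask[b1:b2] <- TRUE
  }
  domain_solution(labels, mask = mask)
}

#' Write / read a correlation matrix as dense TSV (mask in a sidecar file)
#'
#' `write_correlation()` stores the full matrix as a tab-separated dense
#' numeric table and the validity mask (plus `sigma_c` and the band width, if
#' set) in `<path>.meta`.  `read_correlation()` reverses it.
#'
#' @param cm A [correlation_matrix()].
#' @param path Output TSV path.
#' @export
write_correlation <- function(cm, path) {
  stopifnot(inherits(cm, "correlation_matrix"))
  utils::write.table(cm$C, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  meta <- c(sprintf("mask\t%s", paste(as.integer(cm$mask), collapse = ",")),
            sprintf("sigma_c\t%s", format(cm$sigma_c, digits = 17)),
            sprintf("band_bins\t%d", cm$band_bins))
  if (!is.null(cm$binning))
    meta <- c(meta, sprintf("chromosome\t%s", cm$binning$chromosome),
              sprintf("bin_size\t%d", cm$binning$bin_size),
              sprintf("start_offset\t%s", format(cm$binning$start_offset,
                                                 scientific = FALSE)))
  writeLines(meta, paste0(path, ".meta"))
  invisible(NULL)
}

#' @rdname write_correlation
#' @param path TSV path previously written by `write_correlation()`.
#' @export
read_correlation <- function(path) {
  C <- as.matrix(utils::read.table(path, sep = "\t", header = FALSE))
  dimnames(C) <- NULL
  mask <- NULL; sigma_c <- NA_real_; band_bins <- 0L; binning <- NULL
  metapath <- paste0(path, ".meta")
  if (file.exists(metapath)) {
    kv <- strsplit(readLines(metapath), "\t")
    meta <- stats::setNames(vapply(kv, `[`, "", 2L), vapply(kv, `[`, "", 1L))
    if ("mask" %in% names(meta))
      mask <- as.logical(as.integer(strsplit(meta[["mask"]], ",")[[1L]]))
    if ("sigma_c" %in% names(meta)) sigma_c <- as.numeric(meta[["sigma_c"]])
    if ("band_bins" %in% names(meta)) band_bins <- as.integer(meta[["band_bins"]])
    if ("bin_size" %in% names(meta))
      binning <- genomic_binning(meta[["chromosome"]],
                                 as.integer(meta[["bin_size"]]), nrow(C),
                                 as.numeric(meta[["start_offset"]]))
  }
  correlation_matrix(C, binning = binning, mask = mask, sigma_c = sigma_c,
                     band_bins = band_bins)
}

#' Read a genomic interval track (BED / bedGraph / narrowPeak)
#'
#' Thin wrapper over `rtracklayer::import()` returning the plain
#' `data.frame(start, end, value)` accepted by [bin_signal_track()].  For BED
#' input the score column is used as the value; for narrowPeak the
#' signalValue column.
#'
#' @param path Track file path.
#' @param format One of `"auto"`, `"bed"`, `"bedGraph"`, `"narrowPeak"`.
#' @param chromosome If given, keep only intervals on this chromosome.
#' @return `data.frame` with columns `start`, `end`, `value`.
#' @export
read_track <- function(path, format = c("auto", "bed", "bedGraph", "narrowPeak"),
                       chromosome = NULL) {
  format <- match.arg(format)
  if (!requireNamespace("rtracklayer", quietly = TRUE))
    stop("reading track files requires the 'rtracklayer' package")
  if (format == "auto") {
    format <- switch(tolower(tools::file_ext(path)),
                     bedgraph = "bedGraph", narrowpeak = "narrowPeak", "bed")
  }
  gr <- if (format == "narrowPeak") {
    rtracklayer::import(path, format = "BED",
                        extraCols = c(signalValue = "numeric",
                                      pValue = "numeric", qValue = "numeric",
                                      peak = "integer"))
  } else {
    rtracklayer::import(path, format = format)
  }
  df <- as.data.frame(gr)
  value <- if ("signalValue" %in% names(df)) df$signalValue
           else if ("score" %in% names(df)) df$score
           else rep(1, nrow(df))
  out <- data.frame(chrom = as.character(df$seqnames),
                    start = df$start - 1L,  # back to 0-based half-open
                    end = df$end, value = value)
  if (!is.null(chromosome)) out <- out[out$chrom == chromosome, , drop = FALSE]
  out[, c("start", "end", "value")]
}
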