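test_that("triplet input is mirrored across the diagonal", {
  f <- write_tmp(c("0\t0\t5", "0\t50000\t2", "50000\t50000\t5"))
  m <- read_contact_map(f, bin_size = 50000)
  expect_equal(m$counts, matrix(c(5, 2, 2, 5), 2, 2))
  expect_equal(m$binning$n_bins, 2L)
  # unseen pairs are zero; mirroring only fills the transposed entry
  f2 <- write_tmp(c("0\t0\t5", "0\t50000\t2"))
  m2 <- read_contact_map(f2, bin_size = 50000)
  expect_equal(m2$counts, matrix(c(5, 2, 2, 0), 2, 2))
})

test_that("read_contact_map rejects bad input", {
  expect_error(read_contact_map(write_tmp(character(0)), 50000), "no records")
  expect_error(read_contact_map(write_tmp("0\tx\t5"), 50000), "non-numeric")
  expect_error(read_contact_map(write_tmp("0\t25000\t5"), 50000),
               "multiple of bin_size")
  f <- write_tmp(c("1\t2\t0\t0", "2.0001\t1\t0\t0", "0\t0\t1\t0", "0\t0\t0\t1"))
  expect_error(read_contact_map(f, 50000), "not symmetric")
})

test_that("dense input round-trips through the triplet writer", {
  truth <- ds(rep(1:2, each = 5))
  Cm <- sample_signals(truth, g = 2, n_samples = 10, seed = 1)$C_model
  map <- synth_hic(Cm, n_reads_per_pair = 1000, seed = 2)
  f <- tempfile()
  write_contact_map(map, f)
  back <- read_contact_map(f, bin_size = map$binning$bin_size,
                           n_bins = map$binning$n_bins)
  expect_equal(back$counts, map$counts)
})

test_that("low-coverage masking flags empty bins only", {
  counts <- matrix(1, 10, 10)
  counts[3, ] <- 0; counts[, 3] <- 0
  counts[7, ] <- 0; counts[, 7] <- 0
  counts[9, ] <- 0; counts[, 9] <- 0
  m <- new_contact_map_for_test(counts)
  masked <- mask_low_coverage(m, 0)
  expect_equal(which(!masked$mask), c(3L, 7L, 9L))
  dense <- mask_low_coverage(new_contact_map_for_test(matrix(1, 4, 4)), 0)
  expect_true(all(dense$mask))
  expect_error(mask_low_coverage(new_contact_map_for_test(matrix(0, 3, 3)), 0),
               "no usable bins")
})

test_that("KR balancing matches hand-solved 2x2 cases and hits row sums 1", {
  m <- new_contact_map_for_test(matrix(c(0, 2, 2, 0), 2, 2))
  b <- kr_normalize(m)
  expect_equal(b$counts, matrix(c(0, 1, 1, 0), 2, 2), tolerance = 1e-6)
  expect_equal(b$balance_vector, rep(1 / sqrt(2), 2), tolerance = 1e-6)

  b2 <- kr_normalize(new_contact_map_for_test(matrix(1, 2, 2)))
  expect_equal(b2$counts, matrix(0.5, 2, 2), tolerance = 1e-6)

  # already row-stochastic symmetric: fixed point with v = 1
  A <- matrix(c(0.5, 0.5, 0.5, 0.5), 2, 2)
  b3 <- kr_normalize(new_contact_map_for_test(A))
  expect_equal(b3$balance_vector, c(1, 1), tolerance = 1e-5)

  set.seed(42)
  n <- 30
  X <- matrix(stats::rexp(n * n), n, n)
  M <- X + t(X)
  b4 <- kr_normalize(new_contact_map_for_test(M))
  expect_true(all(abs(rowSums(b4$counts) - 1) < 1e-6))
})

test_that("KR balancing is scale invariant and detects disconnected graphs", {
  set.seed(7)
  X <- matrix(stats::rexp(100), 10, 10)
  M <- X + t(X)
  b1 <- kr_normalize(new_contact_map_for_test(M))
  b2 <- kr_normalize(new_contact_map_for_test(17.3 * M))
  expect_equal(b1$counts, b2$counts, tolerance = 1e-6)

  blockdiag <- matrix(0, 4, 4)
  blockdiag[1:2, 1:2] <- 1; blockdiag[3:4, 3:4] <- 1
  expect_error(kr_normalize(new_contact_map_for_test(blockdiag)), "reducible")
})

test_that("expected profile averages per distance and carries values forward", {
  # N = 4 toy: distance-1 values {1, 2, 3} -> expected[1] = 2
  M <- matrix(0.01, 4, 4)
  M[1, 2] <- M[2, 1] <- 1
  M[2, 3] <- M[3, 2] <- 2
  M[3, 4] <- M[4, 3] <- 3
  b <- balanced_map_for_test(M)
  e <- expected_profile(b, smoothing = "none")
  expect_equal(e[2], 2)

  f <- function(d) 1 / (1 + d)
  Mf <- outer(1:6, 1:6, function(i, j) f(abs(i - j)))
  ef <- expected_profile(balanced_map_for_test(Mf), smoothing = "none")
  expect_equal(ef, f(0:5))

  ec <- expected_profile(balanced_map_for_test(matrix(0.2, 5, 5)))
  expect_equal(ec, rep(0.2, 5))
})

test_that("O/E Pearson correlation finds block structure and masks flat rows", {
  # two anticorrelated row patterns -> negative cross-block correlation
  n <- 8
  lab <- rep(1:2, each = 4)
  base <- outer(1:n, 1:n, function(i, j) 1 / (1 + abs(i - j)))
  mod <- ifelse(outer(lab, lab, "=="), 1.6, 0.4)
  M <- base * mod
  M <- (M + t(M)) / 2
  b <- balanced_map_for_test(M)
  ex <- expected_profile(b, smoothing = "none")
  oe <- oe_pearson(b, ex)
  expect_true(all(oe$C[1:4, 5:8] < 0))
  expect_equal(diag(oe$C), rep(1, n))
  off <- oe$C[upper.tri(oe$C)]
  expect_true(all(off >= -1 & off <= 1))
  expect_equal(oe$C, t(oe$C))
  # full-matrix oracle: Pearson correlation of explicitly built O/E rows
  OE <- M / outer(1:n, 1:n, function(i, j) ex[abs(i - j) + 1])
  expect_equal(unname(oe$C), unname(stats::cor(t(OE))))

  # exactly distance-dependent map: O/E is constant, all rows zero-variance
  b0 <- balanced_map_for_test(base)
  expect_warning(oe0 <- oe_pearson(b0, expected_profile(b0, smoothing = "none")),
                 "zero-variance")
  expect_true(all(!oe0$mask))
})

test_that("interval tracks are binned with straddle splitting and averaging", {
  bn <- genomic_binning("chr1", 50000, 10)
  t1 <- bin_signal_track(data.frame(start = 150000, end = 160000, value = 7), bn)
  expect_equal(t1$values[4], 7)

  t2 <- bin_signal_track(data.frame(start = 175000, end = 225000, value = 8), bn)
  expect_equal(t2$values[4], 4)
  expect_equal(t2$values[5], 4)

  t3 <- bin_signal_track(data.frame(start = c(0, 10000), end = c(5000, 15000),
                                    value = c(2, 4)), bn)
  expect_equal(t3$values[1], 3)

  expect_warning(bin_signal_track(data.frame(start = 9e6, end = 9.1e6, value = 1), bn),
                 "outside")
})

test_that("track binning conserves signal mass without multi-hit bins", {
  set.seed(11)
  bn <- genomic_binning("chr1", 1000, 50)
  starts <- seq(0, 49000, by = 5000)  # one interval per fifth bin
  iv <- data.frame(start = starts + 100, end = starts + 900,
                   value = stats::runif(length(starts)))
  tr <- bin_signal_track(iv, bn)
  expect_equal(sum(tr$values), sum(iv$value))
})

test_that("domain BED files round-trip, merging runs and naming masked bins", {
  bn <- genomic_binning("chr2", 50000, 3)
  s <- ds(c(1, 1, 2))
  f <- tempfile(fileext = ".bed")
  write_domains(s, bn, f)
  rec <- read.table(f, sep = "\t")
  expect_equal(nrow(rec), 2L)
  expect_equal(rec$V2, c(0, 100000))
  expect_equal(rec$V3, c(100000, 150000))

  s2 <- ds(c(1, 2, 1))
  write_domains(s2, bn, f)
  rec2 <- read.table(f, sep = "\t")
  expect_equal(nrow(rec2), 3L)
  expect_equal(as.character(rec2$V4), c("1", "2", "1"))

  labels <- c(1, 1, 2, NA, 2, 3)
  s3 <- domain_solution(labels)
  bn6 <- genomic_binning("chr2", 50000, 6)
  write_domains(s3, bn6, f)
  rec3 <- read.table(f, sep = "\t")
  expect_true("." %in% rec3$V4)
  back <- read_domains(f, bn6)
  expect_equal(back$labels, s3$labels)
  expect_equal(back$mask, s3$mask)
})

test_that("correlation matrices round-trip through TSV with mask sidecar", {
  cm <- noisy_correlation(6, seed = 3)
  cm$mask[4] <- FALSE
  cm$C[4, ] <- NA; cm$C[, 4] <- NA; diag(cm$C) <- 1
  cm <- correlation_matrix(cm$C, mask = cm$mask, sigma_c = 0.3, band_bins = 1L)
  f <- tempfile(fileext = ".tsv")
  write_correlation(cm, f)
  back <- read_correlation(f)
  expect_equal(back$C, cm$C, tolerance = 1e-12)
  expect_equal(back$mask, cm$mask)
  expect_equal(back$sigma_c, 0.3)
  expect_equal(back$band_bins, 1L)
})
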