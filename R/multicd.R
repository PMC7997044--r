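#' Fit multi-scale chromatin domains to a correlation matrix
#'
#' The main fitting function.  Takes a pairwise correlation matrix (or a raw
#' Hi-C contact map, which is first passed through the polymer preprocessing
#' chain) and minimizes the penalized group-model objective
#' `H_lambda(s | C) = E(s | C) + lambda * K(s)` by simulated annealing at
#' each requested `lambda`, returning the family of domain solutions.
#'
#' @param x A [correlation_matrix()], a plain symmetric numeric matrix with
#'   unit diagonal, or a raw contact map (class `"raw_contact_map"`).
#' @param lambda Numeric vector of resolution penalties (ascending); a
#'   single value fits one solution.
#' @param schedule An [anneal_schedule()].
#' @param band_width Optional near-diagonal band (bp) to exclude before
#'   fitting (used for compartment-style inference).
#' @param warm_start Warm-start successive lambdas (default `TRUE`).
#' @param seed Optional integer seed.
#' @param ... Passed to [preprocess_hic()] when `x` is a raw contact map.
#'
#' @return An object of class `"multicd"`: list with elements `C` (the
#'   [correlation_matrix()] used), `family` (a `"solution_family"`),
#'   `lambdas`, `schedule` and `call`.
#'
#' @examples
#' truth <- domain_solution(rep(1:4, each = 10))
#' C <- sample_signals(truth, g = 2, n_samples = 300, seed = 1)$C_hat
#' fit <- multicd(C, lambda = 0, seed = 1)
#' summary(fit)
#' binary_similarity(domains(fit), truth)
#' @export
multicd <- function(x, lambda = 0, schedule = anneal_schedule(),
                    band_width = NULL, warm_start = TRUE, seed = NULL, ...) {
  cl <- match.call()
  cm <- if (inherits(x, "correlation_matrix")) {
    x
  } else if (inherits(x, "raw_contact_map")) {
    preprocess_hic(x, ...)
  } else if (is.matrix(x)) {
    correlation_matrix(x)
  } else {
    stop("'x' must be a correlation matrix or a raw contact map")
  }
  if (!is.null(band_width)) cm <- band_mask(cm, band_width)
  lambda <- sort(unique(as.numeric(lambda)))
  fam <- sweep_lambda(cm, lambda, schedule = schedule,
                      warm_start = warm_start, seed = seed)
  structure(list(C = cm, family = fam, lambdas = lambda,
                 schedule = schedule, call = cl),
            class = "multicd")
}

# pick the family entry for a lambda (default: first)
.pick <- function(object, lambda = NULL) {
  if (is.null(lambda)) return(1L)
  i <- match(lambda, object$lambdas)
  if (is.na(i)) stop("no solution at lambda = ", lambda,
                     "; available: ", paste(object$lambdas, collapse = ", "))
  i
}

#' Extract a fitted domain solution
#'
#' @param object A `"multicd"` fit.
#' @param lambda Which penalty's solution (default: the first).
#' @return A [domain_solution()].
#' @export
domains <- function(object, lambda = NULL) {
  stopifnot(inherits(object, "multicd"))
  object$family$solutions[[.pick(object, lambda)]]
}

#' @export
print.multicd <- function(x, ...) {
  cat("Multi-scale chromatin domain fit\n")
  cat(sprintf("  %d bins (%d valid), %d lambda value(s)\n",
              length(x$C$mask), sum(x$C$mask), length(x$lambdas)))
  if (x$C$band_bins > 0L)
    cat(sprintf("  diagonal band of %d bins excluded\n", x$C$band_bins))
  print(x$family$diagnostics, row.names = FALSE)
  invisible(x)
}

#' @export
summary.multicd <- function(object, ...) {
  d <- object$family$diagnostics
  structure(list(diagnostics = d, call = object$call,
                 n_bins = length(object$C$mask), n_valid = sum(object$C$mask)),
            class = "summary.multicd")
}

#' @export
print.summary.multicd <- function(x, ...) {
  cat("Call: ", deparse(x$call), "\n")
  cat(sprintf("%d bins (%d valid)\n\n", x$n_bins, x$n_valid))
  print(x$diagnostics, row.names = FALSE)
  invisible(x)
}

#' @export
coef.multicd <- function(object, lambda = NULL, ...) {
  s <- domains(object, lambda)
  st <- domain_stats(s, object$C)
  stats::setNames(st$g_hat, paste0("domain", st$domain))
}

#' @export
fitted.multicd <- function(object, lambda = NULL, ...) {
  s <- domains(object, lambda)
  model_correlation(s, coef(object, lambda))
}

#' @export
residuals.multicd <- function(object, lambda = NULL, ...) {
  object$C$C - fitted(object, lambda)
}

#' Simulate signals from a fitted domain model
#'
#' Draws genomic-state samples from the group model at the fitted partition
#' and strengths (see [sample_signals()]).
#'
#' @param object A `"multicd"` fit.
#' @param nsim Number of samples.
#' @param seed Optional integer seed.
#' @param lambda Which solution to simulate from.
#' @param ... Unused.
#' @return The `n x N` sample matrix (over valid bins).
#' @export
simulate.multicd <- function(object, nsim = 100, seed = NULL, lambda = NULL,
                             ...) {
  s <- domains(object, lambda)
  sample_signals(s, g = coef(object, lambda), n_samples = nsim, seed = seed)$x
}

#' Plot a domain fit
#'
#' `type = "matrix"` draws the correlation matrix with the fitted domain
#' boundaries overlaid; `type = "diagnostics"` plots mean domain size and
#' generalized domain count against lambda.
#'
#' @param x A `"multicd"` fit.
#' @param type `"matrix"` or `"diagnostics"`.
#' @param lambda Which solution to draw (matrix plot).
#' @param ... Passed to [graphics::image()].
#' @export
plot.multicd <- function(x, type = c("matrix", "diagnostics"), lambda = NULL,
                         ...) {
  type <- match.arg(type)
  if (type == "diagnostics") {
    d <- x$family$diagnostics
    op <- graphics::par(mfrow = c(1, 2))
    on.exit(graphics::par(op))
    graphics::plot(d$lambda, d$mean_size, type = "b", xlab = expression(lambda),
                   ylab = "mean domain size (bins)")
    graphics::plot(d$lambda, d$genK, type = "b", xlab = expression(lambda),
                   ylab = "generalized domain count K(s)")
    return(invisible(x))
  }
  s <- domains(x, lambda)
  C <- x$C$C
  n <- nrow(C)
  pal <- grDevices::hcl.colors(64, "RdBu", rev = TRUE)
  graphics::image(seq_len(n), seq_len(n), C[, n:1], col = pal,
                  zlim = c(-1, 1), xlab = "bin", ylab = "bin", useRaster = TRUE,
                  ...)
  lab <- s$labels
  bd <- which(diff(lab) != 0 | diff(s$mask) != 0) + 0.5
  graphics::abline(v = bd, h = n - bd + 1, col = "black", lwd = 0.5)
  invisible(x)
}
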