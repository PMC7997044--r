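#' Simulated-annealing schedule
#'
#' Geometric cooling: starting from `T0`, the temperature is multiplied by
#' `alpha` after every `sweeps_per_T` full Metropolis sweeps until it falls
#' below `T_min`; the whole anneal is repeated `n_restarts` times from
#' independent starts and the best state ever visited is returned.
#'
#' @param T0 Initial temperature (> `T_min`).
#' @param alpha Cooling factor in (0, 1).
#' @param sweeps_per_T Sweeps per temperature level (>= 1).
#' @param T_min Final temperature (> 0).
#' @param n_restarts Independent restarts (>= 1).
#'
#' @return An object of class `"anneal_schedule"`.
#' @export
anneal_schedule <- function(T0 = 1.0, alpha = 0.9, sweeps_per_T = 20L,
                            T_min = 1e-3, n_restarts = 5L) {
  stopifnot(T0 > T_min, T_min > 0, alpha > 0, alpha < 1,
            sweeps_per_T >= 1, n_restarts >= 1)
  structure(list(T0 = T0, alpha = alpha, sweeps_per_T = as.integer(sweeps_per_T),
                 T_min = T_min, n_restarts = as.integer(n_restarts)),
            class = "anneal_schedule")
}

# run a function with a locally seeded RNG, restoring global state
.with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) stats::runif(1)
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  expr
}

#' One Metropolis sweep over all valid sites
#'
#' Visits every valid site once in random order; for each site proposes a new
#' label drawn uniformly from the existing labels (other than the current
#' one) plus one fresh label, and accepts with probability
#' `min(1, exp(-dH/T) * K/K')` — the Metropolis rule with the
#' Metropolis-Hastings factor `K/K'` that accounts for the change in the
#' number of available proposals when the domain count changes, so that the
#' chain's stationary distribution is exactly `exp(-H/T)` over partitions.
#' Emptied domains are deleted and labels re-canonicalized.
#'
#' @param s A [domain_solution()].
#' @param cm A [correlation_matrix()].
#' @param lambda Resolution penalty.
#' @param T Temperature (> 0).
#' @param nsweeps Number of sweeps to run (default 1).
#' @param hastings Apply the proposal-count correction (default `TRUE`).
#'
#' @return A list with the updated `solution`, the number of `accepted`
#'   moves, and the current objective `H`.
#' @export
metropolis_sweep <- function(s, cm, lambda = 0, T = 1, nsweeps = 1L,
                             hastings = TRUE) {
  stopifnot(T > 0)
  A <- evidence_matrix(cm)
  lab <- .valid_labels(s, cm)
  res <- mcd_sweep_cpp(A, lab, lambda, T, as.integer(nsweeps), hastings)
  labels <- rep(NA_integer_, length(s$labels))
  labels[s$mask] <- res$labels
  list(solution = domain_solution(labels, mask = s$mask, lambda = lambda,
                                  objective = res$H),
       accepted = res$accepted, H = res$H)
}

#' Minimize the penalized objective by simulated annealing
#'
#' Runs `n_restarts` independent anneals (each starting from all-singletons
#' unless `init` is given, in which case the first restart is warm-started)
#' and returns the best-`H` partition ever visited.
#'
#' @param cm A [correlation_matrix()].
#' @param lambda Resolution penalty (>= 0).
#' @param schedule An [anneal_schedule()].
#' @param init Optional [domain_solution()] used to warm-start the first
#'   restart.
#' @param seed Optional integer seed (global RNG state is restored on exit).
#'
#' @return A [domain_solution()] with `lambda` and `objective` filled in and
#'   attribute `"trace"` holding the best-so-far objective after each
#'   temperature level of the winning restart.
#' @export
anneal <- function(cm, lambda = 0, schedule = anneal_schedule(), init = NULL,
                   seed = NULL) {
  stopifnot(inherits(cm, "correlation_matrix"), lambda >= 0)
  .with_seed(seed, {
    A <- evidence_matrix(cm)
    nv <- nrow(A)
    best <- NULL
    for (r in seq_len(schedule$n_restarts)) {
      lab0 <- if (r == 1L && !is.null(init)) .valid_labels(init, cm) else seq_len(nv)
      res <- mcd_anneal_cpp(A, lab0, lambda, schedule$T0, schedule$alpha,
                            schedule$sweeps_per_T, schedule$T_min, TRUE)
      if (is.null(best) || res$best_H < best$best_H) best <- res
    }
    labels <- rep(NA_integer_, length(cm$mask))
    labels[cm$mask] <- best$labels
    out <- domain_solution(labels, mask = cm$mask, lambda = lambda,
                           objective = best$best_H)
    attr(out, "trace") <- best$trace
    out
  })
}

#' Anneal across a grid of resolution penalties
#'
#' Solves the domain-inference problem at each `lambda` in ascending order,
#' optionally warm-starting each anneal from the previous solution (as one of
#' the restarts), and collects per-solution diagnostics: domain count `K`,
#' generalized count `K(s)`, mean domain size, index of dispersion `D`, and
#' (if `reference` is supplied) the normalized mutual information between the
#' reference matrix and each solution.
#'
#' @param cm A [correlation_matrix()].
#' @param lambdas Ascending numeric vector of penalties.
#' @param schedule An [anneal_schedule()].
#' @param warm_start Warm-start each anneal from the previous solution
#'   (default `TRUE`).
#' @param reference Optional symmetric matrix for [nmi()] diagnostics.
#' @param seed Optional integer seed.
#'
#' @return An object of class `"solution_family"`: a list with `solutions`
#'   (one [domain_solution()] per lambda) and `diagnostics` (a `data.frame`).
#' @export
sweep_lambda <- function(cm, lambdas, schedule = anneal_schedule(),
                         warm_start = TRUE, reference = NULL, seed = NULL) {
  stopifnot(!is.unsorted(lambdas, strictly = TRUE))
  .with_seed(seed, {
    sols <- vector("list", length(lambdas))
    prev <- NULL
    for (i in seq_along(lambdas)) {
      sols[[i]] <- anneal(cm, lambda = lambdas[i], schedule = schedule,
                          init = if (warm_start) prev else NULL)
      prev <- sols[[i]]
    }
    diag_df <- do.call(rbind, lapply(seq_along(lambdas), function(i) {
      s <- sols[[i]]
      lab <- .valid_labels(s)
      sizes <- tabulate(lab)
      data.frame(
        lambda = lambdas[i], H = s$objective,
        K = length(sizes), genK = generalized_K(s),
        mean_size = mean(sizes),
        dispersion = .dispersion(sizes, bin_size = if (!is.null(cm$binning))
          cm$binning$bin_size else NA_integer_),
        nmi = if (is.null(reference)) NA_real_ else nmi(reference, s)
      )
    }))
    structure(list(solutions = sols, lambdas = lambdas,
                   diagnostics = diag_df),
              class = "solution_family")
  })
}

#' @export
print.solution_family <- function(x, ...) {
  cat(sprintf("<solution family> %d lambda values\n", length(x$lambdas)))
  print(x$diagnostics, row.names = FALSE)
  invisible(x)
}

#' Secondary (compartment) inference
#'
#' Compartments are modeled as a secondary, typically non-local partition
#' that coexists with the primary (TAD-scale) solution.  Two routes are
#' supported: `mode = "band"` anneals on the correlation matrix with a
#' near-diagonal band removed (so only long-range, checkerboard evidence
#' remains); `mode = "residual"` anneals on the residual correlation left
#' after subtracting the fitted primary structure
#' (see [residual_correlation()]).
#'
#' @param cm A [correlation_matrix()].
#' @param lambda Resolution penalty for the secondary anneal.
#' @param schedule An [anneal_schedule()].
#' @param mode `"band"` or `"residual"`.
#' @param band_width Excluded band half-width in bp (mode `"band"`).
#' @param primary Primary [domain_solution()] (required for mode
#'   `"residual"`).
#' @param g_tilde Optional primary strengths entering the residual transform
#'   (default: [estimate_primary_strengths()], which corrects the fitted
#'   strengths for the shared secondary component).
#' @param seed Optional integer seed.
#'
#' @return A [domain_solution()]; non-contiguous domains are expected.
#' @export
infer_compartments <- function(cm, lambda = 0, schedule = anneal_schedule(),
                               mode = c("band", "residual"),
                               band_width = 2e6, primary = NULL,
                               g_tilde = NULL, seed = NULL) {
  mode <- match.arg(mode)
  target <- if (mode == "band") {
    band_mask(cm, band_width)
  } else {
    if (is.null(primary)) stop("mode 'residual' requires a primary solution")
    if (is.null(g_tilde)) g_tilde <- estimate_primary_strengths(cm, primary)
    residual_correlation(cm, primary, g_tilde)
  }
  anneal(target, lambda = lambda, schedule = schedule, seed = seed)
}

#' Enumerate all partitions of n items
#'
#' Generates every set partition of `n` items as restricted-growth label
#' vectors (canonical form).  Intended for exhaustive verification on small
#' problems (`Bell(8) = 4140`, `Bell(12)` is already 4.2 million).
#'
#' @param n Number of items (kept small; `n <= 12` enforced).
#' @return A list of integer label vectors.
#' @export
enumerate_partitions <- function(n) {
  stopifnot(n >= 1, n <= 12)
  out <- list()
  rec <- function(labels, kmax) {
    i <- length(labels) + 1L
    if (i > n) {
      out[[length(out) + 1L]] <<- labels
      return(invisible(NULL))
    }
    for (k in seq_len(kmax + 1L)) rec(c(labels, k), max(kmax, k))
  }
  rec(integer(0), 0L)
  out
}

#' Exhaustive minimization of the penalized objective
#'
#' Brute-force search over all partitions of the valid bins; the independent
#' oracle against which the annealer is validated on small instances.
#'
#' @param cm A [correlation_matrix()] with at most 12 valid bins.
#' @param lambda Resolution penalty.
#' @return A [domain_solution()] achieving the global minimum of `H`.
#' @export
exhaustive_minimum <- function(cm, lambda = 0) {
  nv <- sum(cm$mask)
  parts <- enumerate_partitions(nv)
  best <- NULL
  bestH <- Inf
  for (p in parts) {
    labels <- rep(NA_integer_, length(cm$mask))
    labels[cm$mask] <- p
    s <- domain_solution(labels, mask = cm$mask)
    H <- objective(s, cm, lambda)
    if (H < bestH - 1e-12) {
      bestH <- H
      best <- s
    }
  }
  best$lambda <- lambda
  best$objective <- bestH
  best
}

# index of dispersion of domain sizes; sizes reported in Mb when a bin size
# is available, otherwise in bins
.dispersion <- function(sizes, bin_size = NA_integer_) {
  x <- if (is.na(bin_size)) sizes else sizes * bin_size / 1e6
  m <- mean(x)
  v <- mean((x - m)^2)  # population variance
  if (m == 0) return(0)
  v / m
}
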