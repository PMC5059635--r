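#' Statistical inefficiency of a correlated time series
#'
#' g = 1 + 2 * sum of the normalized autocorrelation function, accumulated
#' with the usual initial-positive-sequence windowing (summation stops at
#' the first non-positive autocorrelation), so n/g is the effective number
#' of independent samples.
#'
#' @param x Numeric series.
#' @param max_lag Largest lag considered; default `min(n - 1, 10000)`.
#' @return g >= 1 (dimensionless).
#' @export
statistical_inefficiency <- function(x, max_lag = NULL) {
  n <- length(x)
  if (n < 3L) return(1)
  v <- stats::var(x)
  if (v == 0) return(1)
  if (is.null(max_lag)) max_lag <- min(n - 1L, 10000L)
  rho <- stats::acf(x, lag.max = max_lag, plot = FALSE,
                    demean = TRUE)$acf[-1]
  g <- 1
  for (t in seq_along(rho)) {
    if (rho[t] <= 0) break
    g <- g + 2 * rho[t] * (1 - t / n)
  }
  max(1, g)
}

#' Bootstrap per-bin uncertainties for a WHAM PMF
#'
#' Per-window statistical inefficiencies g_i are estimated from the
#' trajectories' integrated autocorrelation times; each bootstrap replicate
#' redraws every window's histogram as a multinomial over its observed bin
#' frequencies with the effective sample size n_i/g_i, re-solves WHAM
#' (warm-started from the reference solution), re-anchors the replicate to
#' the bulk, and the per-bin standard error is the standard deviation of
#' w(z) across replicates. Fixed seed gives bit-reproducible errors.
#'
#' @param series The list of `umbrella_series` behind `histograms` (used
#'   only for the autocorrelation analysis), or `NULL` to assume
#'   uncorrelated samples (g = 1).
#' @param histograms The [build_histograms()] result.
#' @param solution The converged [solve_wham()] reference solution.
#' @param n_boot Number of bootstrap replicates (>= 20). Default 50.
#' @param seed Integer seed.
#' @param bulk_range Bulk anchor range applied to every replicate (and to
#'   the returned profile). If `NULL` the returned profile stays raw and
#'   replicates are gauged to their mean over supported bins instead.
#' @param burn_in_fraction Burn-in used when the histograms were built
#'   (so the inefficiency is estimated on the same retained samples).
#' @param tolerance WHAM tolerance for replicate solves. Default 1e-6
#'   (replicate noise dominates well before that).
#' @return A `pmf_profile` with the `stderr` column filled, plus attributes
#'   `inefficiency` (per-window g) and `short_series` (windows whose series
#'   are shorter than 10 g, flagged with a warning).
#' @export
estimate_uncertainty <- function(series, histograms, solution, n_boot = 50L,
                                 seed = 1L, bulk_range = NULL,
                                 burn_in_fraction = 2 / 22,
                                 tolerance = 1e-6) {
  stopifnot(inherits(histograms, "wham_histograms"),
            inherits(solution, "wham_solution"), n_boot >= 20L)
  W <- nrow(histograms$counts)
  if (is.null(series)) {
    g <- rep(1, W)
  } else {
    stopifnot(length(series) == W)
    g <- vapply(series, function(s) {
      n <- length(s$samples)
      drop <- ceiling(burn_in_fraction * n)
      statistical_inefficiency(s$samples[(drop + 1L):n])
    }, 0)
  }
  n_eff <- pmax(2L, round(histograms$n_total / g))
  short <- which(!is.null(series) &
                   histograms$n_total < 10 * g)
  if (length(short) > 0L)
    warning("series shorter than 10x their correlation time in window(s) ",
            paste(short, collapse = ", "),
            "; uncertainties there are unreliable")
  probs <- histograms$counts / histograms$n_total
  set.seed(as.integer(seed))
  wmat <- matrix(NA_real_, nrow = n_boot, ncol = length(histograms$mids))
  hb <- histograms
  for (b in seq_len(n_boot)) {
    for (i in seq_len(W))
      hb$counts[i, ] <- as.integer(stats::rmultinom(1L, n_eff[i], probs[i, ]))
    hb$n_total <- rowSums(hb$counts)
    sol_b <- solve_wham(hb, temperature = solution$temperature,
                        tolerance = tolerance,
                        max_iter = 2e4)
    pmf_b <- pmf_from_solution(sol_b, allow_unconverged = TRUE)
    if (!is.null(bulk_range)) {
      pmf_b <- offset_to_bulk(pmf_b, bulk_range)
    } else {
      pmf_b$w <- pmf_b$w - mean(pmf_b$w, na.rm = TRUE)
    }
    wmat[b, ] <- pmf_b$w
  }
  stderr <- apply(wmat, 2, function(col) {
    ok <- is.finite(col)
    if (sum(ok) >= 2L) stats::sd(col[ok]) else NA_real_
  })
  pmf <- pmf_from_solution(solution, allow_unconverged = TRUE)
  if (!is.null(bulk_range)) pmf <- offset_to_bulk(pmf, bulk_range)
  pmf$stderr <- stderr
  attr(pmf, "inefficiency") <- g
  attr(pmf, "short_series") <- short
  pmf
}
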