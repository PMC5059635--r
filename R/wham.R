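#' Solve the WHAM equations for a set of umbrella-window histograms
#'
#' Self-consistent weighted-histogram analysis: with per-bin counts
#' \eqn{n_{im}}, window totals \eqn{N_i}, and bias factors
#' \eqn{c_{im} = \exp[-U_i(z_m)/k_BT]}, iterate
#' \deqn{\rho_m = \frac{\sum_i n_{im}}{\sum_i N_i e^{f_i/k_BT} c_{im}},
#'   \qquad f_i = -k_BT \ln \sum_m \rho_m c_{im}}
#' to self-consistency. The free-energy constants are gauge-fixed to
#' \eqn{f_1 = 0}; convergence is declared when the largest change in any
#' \eqn{f_i} between sweeps falls to `tolerance` (kcal/mol). Direct
#' iteration is optionally wrapped in Anderson acceleration (default on,
#' depth 5), which typically cuts the sweep count by orders of magnitude;
#' an accelerated step that fails to stay finite falls back to the plain
#' update, so the fixed point reached is the same.
#'
#' Windows must share support: the graph whose edges join windows that both
#' populate some bin with at least `min_count` samples must be connected,
#' otherwise the relative free energies of the components are undefined and
#' an error lists the disconnected groups.
#'
#' @param histograms A [build_histograms()] result.
#' @param temperature Temperature in K. Default 310.15.
#' @param tolerance Convergence tolerance on max |delta f_i|, kcal/mol.
#'   Default 1e-7.
#' @param max_iter Maximum sweeps; on exhaustion the solution is returned
#'   with `converged = FALSE` rather than raising, so callers can report
#'   diagnostics. Default 1e5.
#' @param anderson Use Anderson acceleration. Default `TRUE`.
#' @param anderson_depth History depth. Default 5.
#' @param min_count Minimum per-bin count for a bin to count as supported.
#'   Default 1.
#' @return A `wham_solution`: list with `f` (per-window constants,
#'   kcal/mol, `f[1] = 0`), `density` (unnormalized per-bin estimate, 0 on
#'   unsupported bins), `mids`, `support`, `iterations`, `residual`
#'   (kcal/mol), `converged`, plus the temperature and inputs needed
#'   downstream.
#' @export
solve_wham <- function(histograms, temperature = 310.15, tolerance = 1e-7,
                       max_iter = 1e5, anderson = TRUE, anderson_depth = 5L,
                       min_count = 1L) {
  stopifnot(inherits(histograms, "wham_histograms"),
            temperature > 0, tolerance > 0, max_iter >= 1)
  h <- histograms
  kT <- kBT(temperature)
  W <- nrow(h$counts); M <- ncol(h$counts)
  half <- if (h$bias_half) 0.5 else 1.0
  # bias energy U_i(z_m), W x M
  U <- outer(seq_len(W), seq_len(M), function(i, m) {
    half * h$windows$k[i] * (h$mids[m] - h$windows$center[i])^2
  })
  B <- exp(-U / kT)
  N <- h$n_total
  Mcounts <- colSums(h$counts)
  support <- Mcounts >= min_count
  check_window_connectivity(h$counts, min_count)
  Msup <- Mcounts
  Msup[!support] <- 0

  g_update <- function(f) {
    a <- exp(f / kT)                       # W
    denom <- as.vector(crossprod(B, N * a))  # M
    rho <- ifelse(denom > 0, Msup / denom, 0)
    fnew <- -kT * log(as.vector(B %*% rho))
    fnew - fnew[1]
  }

  f <- numeric(W)
  res <- Inf
  it <- 0L
  conv <- FALSE
  hist_f <- list(); hist_g <- list()
  while (it < max_iter) {
    it <- it + 1L
    g <- g_update(f)
    r <- g - f
    res <- max(abs(r))
    if (!is.finite(res)) { # restart from plain state
      f <- numeric(W); hist_f <- list(); hist_g <- list(); next
    }
    if (res <= tolerance) { f <- g; conv <- TRUE; break }
    if (anderson) {
      hist_f <- c(hist_f, list(f)); hist_g <- c(hist_g, list(g))
      keep <- max(1L, length(hist_f) - anderson_depth)
      hist_f <- hist_f[keep:length(hist_f)]
      hist_g <- hist_g[keep:length(hist_g)]
      m <- length(hist_f)
      if (m >= 2L) {
        Rmat <- vapply(seq_len(m), function(j) hist_g[[j]] - hist_f[[j]],
                       numeric(W))
        dR <- Rmat[, -1, drop = FALSE] - Rmat[, -m, drop = FALSE]
        Gmat <- vapply(hist_g, identity, numeric(W))
        dG <- Gmat[, -1, drop = FALSE] - Gmat[, -m, drop = FALSE]
        gamma <- tryCatch(qr.solve(dR, r, tol = 1e-12),
                          error = function(e) NULL)
        cand <- if (is.null(gamma)) g else g - as.vector(dG %*% gamma)
        f <- if (all(is.finite(cand))) cand - cand[1] else g
      } else f <- g
    } else f <- g
  }
  a <- exp(f / kT)
  denom <- as.vector(crossprod(B, N * a))
  density <- ifelse(denom > 0, Msup / denom, 0)
  structure(list(f = f, density = density, mids = h$mids,
                 support = support, counts_per_bin = Mcounts,
                 iterations = it, residual = res, converged = conv,
                 temperature = temperature, tolerance = tolerance,
                 bin_width = h$bin_width, windows = h$windows,
                 bias_half = h$bias_half),
            class = "wham_solution")
}

check_window_connectivity <- function(counts, min_count) {
  W <- nrow(counts)
  occ <- counts >= min_count
  comp <- seq_len(W)
  find <- function(i) { while (comp[i] != i) i <- comp[i]; i }
  for (m in seq_len(ncol(counts))) {
    idx <- which(occ[, m])
    if (length(idx) >= 2L)
      for (j in idx[-1]) {
        a <- find(idx[1]); b <- find(j)
        if (a != b) comp[b] <- a
      }
  }
  roots <- vapply(seq_len(W), find, 0L)
  if (length(unique(roots)) > 1L) {
    groups <- split(seq_len(W), roots)
    stop("umbrella windows do not overlap into one connected set; components: ",
         paste(vapply(groups, function(g) paste(g, collapse = ","), ""),
               collapse = " | "))
  }
  invisible(TRUE)
}

#' @export
print.wham_solution <- function(x, ...) {
  cat(sprintf("WHAM solution: %d windows, %d bins (%d supported)\n",
              length(x$f), length(x$mids), sum(x$support)))
  cat(sprintf("  %s after %d sweeps, final residual %.3g kcal/mol (tol %.1g)\n",
              if (x$converged) "converged" else "NOT converged",
              x$iterations, x$residual, x$tolerance))
  invisible(x)
}

#' Convert a WHAM solution to a PMF profile
#'
#' \eqn{w(z_m) = -k_BT \ln \rho_m} on supported bins; unsupported bins are
#' `NA` (missing), never zero. The profile carries the raw (ungauged)
#' offset until [offset_to_bulk()] anchors it.
#'
#' @param solution A [solve_wham()] result.
#' @param temperature Temperature in K; defaults to the solution's.
#' @param allow_unconverged Set `TRUE` to extract a profile from an
#'   unconverged solution anyway.
#' @return A `pmf_profile` (see [pmf_profile()]).
#' @export
pmf_from_solution <- function(solution, temperature = solution$temperature,
                              allow_unconverged = FALSE) {
  stopifnot(inherits(solution, "wham_solution"))
  if (!solution$converged && !allow_unconverged)
    stop("WHAM solution is not converged (residual ",
         format(solution$residual),
         "); pass allow_unconverged = TRUE to override")
  kT <- kBT(temperature)
  w <- ifelse(solution$support, -kT * log(solution$density), NA_real_)
  pmf_profile(z = solution$mids, w = w,
              n = solution$counts_per_bin,
              temperature = temperature, offset = "raw",
              bin_width = solution$bin_width)
}

#' Construct a PMF profile
#'
#' Container for a tabulated potential of mean force w(z) on a uniform bin
#' grid, with optional per-bin standard errors and an offset convention
#' (`"raw"` until the bulk anchor is applied).
#'
#' @param z Bin centres, Angstrom (strictly increasing).
#' @param w PMF values, kcal/mol (`NA` marks unsupported bins).
#' @param stderr Optional per-bin standard errors, kcal/mol.
#' @param n Optional per-bin sample counts.
#' @param temperature Temperature in K.
#' @param offset `"raw"` or `"bulk-zero"`.
#' @param bin_width Bin width, Angstrom (inferred from `z` if omitted).
#' @param bulk_range Bulk anchor range when `offset = "bulk-zero"`.
#' @return A data frame of class `pmf_profile` with columns `z`, `w`,
#'   `stderr`, `n` and attributes `temperature`, `offset`, `bin_width`,
#'   `bulk_range`.
#' @export
pmf_profile <- function(z, w, stderr = NA_real_, n = NA_integer_,
                        temperature = 310.15, offset = c("raw", "bulk-zero"),
                        bin_width = NULL, bulk_range = NULL) {
  offset <- match.arg(offset)
  stopifnot(is.numeric(z), is.numeric(w), length(z) == length(w),
            !is.unsorted(z, strictly = TRUE), temperature > 0)
  if (is.null(bin_width))
    bin_width <- if (length(z) > 1L) stats::median(diff(z)) else NA_real_
  df <- data.frame(z = z, w = w,
                   stderr = rep_len(stderr, length(z)),
                   n = rep_len(n, length(z)))
  structure(df, class = c("pmf_profile", "data.frame"),
            temperature = temperature, offset = offset,
            bin_width = bin_width, bulk_range = bulk_range)
}

#' @export
print.pmf_profile <- function(x, ...) {
  sup <- !is.na(x$w)
  cat(sprintf("PMF profile: %d bins (%d supported) on [%.2f, %.2f] Angstrom\n",
              nrow(x), sum(sup), min(x$z), max(x$z)))
  cat(sprintf("  offset: %s; T = %.2f K", attr(x, "offset"),
              attr(x, "temperature")))
  if (!is.null(attr(x, "bulk_range")))
    cat(sprintf("; bulk [%.2f, %.2f]", attr(x, "bulk_range")[1],
                attr(x, "bulk_range")[2]))
  cat("\n")
  if (any(sup))
    cat(sprintf("  min w = %.3f kcal/mol at z = %.2f\n",
                min(x$w[sup]), x$z[sup][which.min(x$w[sup])]))
  invisible(x)
}

#' Anchor a PMF to zero in the bulk region
#'
#' Subtracts the mean of w over the declared bulk range so the profile
#' measures free energy relative to the ligand free in bulk — the offset
#' convention required before a dissociation constant can be computed.
#' Standard errors are untouched (a constant shift has no variance of its
#' own here; replicate-level offsetting is handled in
#' [estimate_uncertainty()]).
#'
#' @param pmf A [pmf_profile()].
#' @param bulk_range `c(lo, hi)` in Angstrom; must cover at least 3
#'   supported bins.
#' @return The profile with `offset = "bulk-zero"` and `bulk_range`
#'   recorded.
#' @export
offset_to_bulk <- function(pmf, bulk_range) {
  stopifnot(inherits(pmf, "pmf_profile"), is.numeric(bulk_range),
            length(bulk_range) == 2L, bulk_range[1] < bulk_range[2])
  sel <- pmf$z >= bulk_range[1] & pmf$z <= bulk_range[2] & !is.na(pmf$w)
  if (sum(sel) < 3L)
    stop("bulk range [", bulk_range[1], ", ", bulk_range[2],
         "] covers fewer than 3 supported bins; widen it or check support")
  shift <- mean(pmf$w[sel])
  out <- pmf
  out$w <- pmf$w - shift
  attr(out, "offset") <- "bulk-zero"
  attr(out, "bulk_range") <- as.numeric(bulk_range)
  out
}
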