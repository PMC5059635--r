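#' Histogram umbrella-window trajectories on a shared bin grid
#'
#' Discards an initial burn-in fraction of every series (the first
#' `ceiling(burn_in_fraction * n)` samples; the default 2/22 mirrors
#' dropping the first 2 ns of a 22-ns window and keeping the last 20), then
#' counts the retained samples on one uniform grid shared by all windows.
#' Bins are half-open `[left, right)`; the last bin also includes its right
#' edge, so every in-range sample is counted exactly once. Out-of-range
#' samples are tallied per window and reported in the result (with a
#' warning), never silently dropped.
#'
#' @param series List of `umbrella_series` (see
#'   [sample_biased_trajectory()]).
#' @param bin_width Bin width in Angstrom. Default 0.1.
#' @param burn_in_fraction Fraction of each series discarded from the
#'   start; in `[0, 1)`. Default `2/22`.
#' @param range `"auto"` (span of retained samples, snapped outward to the
#'   bin grid anchored at z = 0) or `c(lo, hi)` in Angstrom.
#' @return A `wham_histograms` object: list with `breaks` (bin edges),
#'   `mids` (bin centres), `counts` (windows x bins integer matrix),
#'   `n_total` (retained samples per window), `windows` (data frame of
#'   centres and force constants), `bias_half`, `out_of_range` (per-window
#'   counts), `bin_width`.
#' @export
build_histograms <- function(series, bin_width = 0.1,
                             burn_in_fraction = 2 / 22, range = "auto") {
  stopifnot(is.list(series), length(series) >= 1L,
            bin_width > 0, burn_in_fraction >= 0, burn_in_fraction < 1)
  retained <- lapply(seq_along(series), function(i) {
    s <- series[[i]]
    if (!inherits(s, "umbrella_series"))
      stop("element ", i, " of `series` is not an umbrella_series")
    n <- length(s$samples)
    drop <- ceiling(burn_in_fraction * n)
    if (drop >= n)
      stop(sprintf("window %d (center %.3f): no samples left after burn-in",
                   i, s$window$center))
    s$samples[(drop + 1L):n]
  })
  if (identical(range, "auto")) {
    lo <- floor(min(vapply(retained, min, 0)) / bin_width) * bin_width
    hi <- ceiling(max(vapply(retained, max, 0)) / bin_width) * bin_width
  } else {
    stopifnot(is.numeric(range), length(range) == 2L, range[1] < range[2])
    lo <- range[1]; hi <- range[2]
  }
  n_bins <- round((hi - lo) / bin_width)
  if (abs(n_bins * bin_width - (hi - lo)) > 1e-8)
    stop("histogram range is not a multiple of the bin width")
  breaks <- lo + bin_width * seq.int(0L, n_bins)
  counts <- matrix(0L, nrow = length(series), ncol = n_bins)
  out_of_range <- integer(length(series))
  for (i in seq_along(retained)) {
    z <- retained[[i]]
    idx <- floor((z - lo) / bin_width) + 1L
    idx[z == breaks[n_bins + 1L]] <- n_bins  # right-closed last bin
    inside <- idx >= 1L & idx <= n_bins & z >= lo & z <= breaks[n_bins + 1L]
    out_of_range[i] <- sum(!inside)
    counts[i, ] <- tabulate(idx[inside], nbins = n_bins)
  }
  if (any(out_of_range > 0L))
    warning(sprintf("%d sample(s) fell outside the histogram range (see $out_of_range)",
                    sum(out_of_range)))
  windows <- data.frame(
    center = vapply(series, function(s) s$window$center, 0),
    k = vapply(series, function(s) s$window$k, 0))
  bias_half <- vapply(series, function(s) isTRUE(s$window$bias_half), TRUE)
  if (length(unique(bias_half)) > 1L)
    stop("windows mix bias conventions (half-factor differs)")
  structure(list(breaks = breaks, mids = (breaks[-1] + breaks[-length(breaks)]) / 2,
                 counts = counts, n_total = rowSums(counts),
                 windows = windows, bias_half = bias_half[1],
                 out_of_range = out_of_range, bin_width = bin_width),
            class = "wham_histograms")
}

#' @export
print.wham_histograms <- function(x, ...) {
  cat(sprintf("Umbrella histograms: %d windows, %d bins of %.3g Angstrom on [%.2f, %.2f]\n",
              nrow(x$counts), ncol(x$counts), x$bin_width,
              x$breaks[1], x$breaks[length(x$breaks)]))
  cat(sprintf("  retained samples per window: %d-%d; out-of-range total: %d\n",
              min(x$n_total), max(x$n_total), sum(x$out_of_range)))
  invisible(x)
}
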