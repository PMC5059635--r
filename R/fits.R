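#' Fit the Hill concentration-response model
#'
#' Least-squares fit of fractional block
#' \eqn{b(c) = 1 / (1 + (IC_{50}/c)^{n_H})} by Levenberg-Marquardt. When no
#' start is given a deterministic multi-start grid (log-spaced IC50 across
#' the tested concentrations, Hill coefficients 0.5-6) seeds the optimizer
#' and the best converged fit is kept, so the result depends only on the
#' data.
#'
#' @param data Data frame with columns `concentration_uM` and
#'   `block_fraction` (at least 3 distinct concentrations, block in
#'   \[0, 1\]).
#' @param start Optional named list `list(ic50 = , n_h = )`.
#' @return A `curve_fit` with parameters `ic50` (uM) and `n_h`.
#' @examples
#' d <- generate_hill_data(0.041, 2.4, c(0.003, 0.01, 0.03, 0.1, 0.3))
#' coef(fit_hill(d))
#' @export
fit_hill <- function(data, start = NULL) {
  data <- check_table(data, c("concentration_uM", "block_fraction"))
  c_ <- data$concentration_uM; b <- data$block_fraction
  if (length(unique(c_)) < 3L)
    stop("need at least 3 distinct concentrations")
  if (any(b < -1e-9 | b > 1 + 1e-9))
    stop("block_fraction values must lie in [0, 1]")
  if (stats::sd(b) == 0)
    stop("degenerate data: block fraction is identical at all concentrations")
  if (is.null(start)) {
    starts <- expand.grid(
      ic50 = exp(seq(log(min(c_)), log(max(c_)), length.out = 7L)),
      n_h = c(0.5, 1, 2, 4, 6))
  } else {
    starts <- data.frame(ic50 = start$ic50, n_h = start$n_h)
  }
  fit_best(data, starts, model = "hill",
           formula = block_fraction ~ 1 / (1 + (ic50 / concentration_uM)^n_h),
           lower = c(ic50 = 1e-12, n_h = 1e-6))
}

#' Fit a single-exponential block time course
#'
#' Least-squares fit of \eqn{I(t) = A e^{-t/\tau} + C}; `tau` is reported
#' as the use-dependent block time constant. The steady-state offset C is
#' included by default (set `offset = FALSE` for a pure exponential); the
#' choice is recorded in the result's model name.
#'
#' @param data Data frame with columns `time_s` (increasing) and `i_norm`.
#' @param offset Include the constant C. Default `TRUE`.
#' @param start Optional named list with `A`, `tau` (and `C`).
#' @return A `curve_fit` with parameters `A`, `tau` (s) and optionally `C`.
#'   Non-decaying data yield `converged = FALSE` rather than an error,
#'   except strictly constant data which are refused.
#' @export
fit_exponential <- function(data, offset = TRUE, start = NULL) {
  data <- check_table(data, c("time_s", "i_norm"))
  if (is.unsorted(data$time_s)) stop("times must be increasing")
  npar <- if (offset) 3L else 2L
  if (nrow(data) < max(3L, npar))
    stop("need at least ", max(3L, npar), " points")
  y <- data$i_norm
  if (stats::sd(y) == 0) stop("degenerate data: constant current")
  if (is.null(start)) {
    C0 <- if (offset) min(y) - 0.05 * abs(min(y)) else 0
    A0 <- max(y) - C0
    pos <- y - C0 > 1e-12 & data$time_s > 0
    tau0 <- if (sum(pos) >= 2L) {
      sl <- stats::coef(stats::lm(log(y[pos] - C0) ~ data$time_s[pos]))[2]
      if (is.finite(sl) && sl < 0) -1 / sl else diff(range(data$time_s)) / 2
    } else diff(range(data$time_s)) / 2
    start <- if (offset) list(A = A0, tau = tau0, C = C0)
             else list(A = A0, tau = tau0)
  }
  fml <- if (offset) i_norm ~ A * exp(-time_s / tau) + C
         else i_norm ~ A * exp(-time_s / tau)
  lower <- if (offset) c(A = -Inf, tau = 1e-12, C = -Inf)
           else c(A = -Inf, tau = 1e-12)
  fit <- fit_best(data, as.data.frame(start),
                  model = if (offset) "exponential+offset" else "exponential",
                  formula = fml, lower = lower)
  # a "decay" fit that ran to the tau bound or has non-positive amplitude
  # did not actually see a decay
  if (fit$converged &&
      (fit$estimate[["tau"]] <= 1e-10 || fit$estimate[["A"]] <= 0))
    fit$converged <- FALSE
  fit
}

#' Fit the Boltzmann activation (g-V) curve
#'
#' Least-squares fit of \eqn{g/g_{max} = g_{max,fit} /
#' (1 + \exp[(V_{1/2} - V)/k_s])}. With the default
#' `fit_gmax = FALSE` the data are taken as already normalized
#' (\eqn{g_{max} = 1}). A positive slope factor means activation with
#' depolarization. Data lying entirely on one side of the midpoint are not
#' refused, but the fit is flagged (`one_sided = TRUE`) and its standard
#' errors will be wide.
#'
#' @param data Data frame with columns `voltage_mV` and `g_norm`
#'   (at least 4 points).
#' @param fit_gmax Also fit the maximal conductance. Default `FALSE`.
#' @param start Optional named list with `v_half`, `slope` (and `g_max`).
#' @return A `curve_fit` with parameters `v_half` (mV), `slope` (mV) and
#'   optionally `g_max`.
#' @export
fit_boltzmann <- function(data, fit_gmax = FALSE, start = NULL) {
  data <- check_table(data, c("voltage_mV", "g_norm"))
  if (nrow(data) < 4L) stop("need at least 4 points")
  if (stats::sd(data$g_norm) == 0) stop("degenerate data: constant conductance")
  if (is.null(start)) {
    gmax0 <- max(data$g_norm)
    v0 <- stats::approx(data$g_norm / gmax0, data$voltage_mV, xout = 0.5,
                        ties = mean)$y
    if (!is.finite(v0)) v0 <- stats::median(data$voltage_mV)
    starts <- expand.grid(v_half = v0 + c(-10, 0, 10),
                          slope = c(2, 5, 10, 20))
    if (fit_gmax) starts$g_max <- gmax0
  } else {
    starts <- as.data.frame(start)
  }
  fml <- if (fit_gmax)
    g_norm ~ g_max / (1 + exp((v_half - voltage_mV) / slope))
  else g_norm ~ 1 / (1 + exp((v_half - voltage_mV) / slope))
  lower <- if (fit_gmax) c(v_half = -Inf, slope = 1e-6, g_max = 1e-9)
           else c(v_half = -Inf, slope = 1e-6)
  fit <- fit_best(data, starts, model = "boltzmann", formula = fml,
                  lower = lower)
  mid <- fit$estimate[["v_half"]]
  fit$one_sided <- all(data$voltage_mV > mid) || all(data$voltage_mV < mid)
  fit
}

check_table <- function(data, cols) {
  data <- as.data.frame(data)
  missing_cols <- setdiff(cols, names(data))
  if (length(missing_cols) > 0L)
    stop("input table lacks column(s): ", paste(missing_cols, collapse = ", "))
  data <- data[stats::complete.cases(data[cols]), , drop = FALSE]
  # fits are invariant to row order; sort on the predictor for stability
  data[order(data[[cols[1]]]), , drop = FALSE]
}

fit_best <- function(data, starts, model, formula, lower) {
  # a perfect (zero-residual) fit can abort nlsLM's model construction at
  # very tight tolerances, so retry each start with the default control
  ctrls <- list(minpack.lm::nls.lm.control(ftol = 1e-14, ptol = 1e-14,
                                           maxiter = 500L),
                minpack.lm::nls.lm.control(maxiter = 500L))
  best <- NULL
  for (s in seq_len(nrow(starts))) {
    fit <- NULL
    for (ctrl in ctrls) {
      fit <- tryCatch(
        suppressWarnings(minpack.lm::nlsLM(formula, data = data,
                                           start = as.list(starts[s, ,
                                                                  drop = FALSE]),
                                           lower = lower, control = ctrl)),
        error = function(e) NULL)
      if (!is.null(fit)) break
    }
    if (is.null(fit)) next
    rss <- sum(stats::residuals(fit)^2)
    if (is.null(best) || rss < best$rss - 1e-15) best <- list(fit = fit,
                                                              rss = rss)
  }
  if (is.null(best)) {
    return(structure(list(model = model, estimate = NULL, stderr = NULL,
                          rss = NA_real_, n = nrow(data), converged = FALSE,
                          diagnostics = "no start converged"),
                     class = "curve_fit"))
  }
  est <- stats::coef(best$fit)
  n <- nrow(data)
  se <- if (n > length(est)) {
    tryCatch(summary(best$fit)$coefficients[, "Std. Error"],
             error = function(e) rep(NA_real_, length(est)))
  } else rep(NA_real_, length(est))
  names(se) <- names(est)
  structure(list(model = model, estimate = est, stderr = se, rss = best$rss,
                 n = n, converged = TRUE, diagnostics = NULL),
            class = "curve_fit")
}

#' @export
print.curve_fit <- function(x, ...) {
  cat(sprintf("%s fit (%d points, RSS %.3g)%s\n", x$model, x$n, x$rss,
              if (x$converged) "" else "  [NOT CONVERGED]"))
  if (!is.null(x$estimate))
    for (p in names(x$estimate))
      cat(sprintf("  %-7s = %.6g%s\n", p, x$estimate[[p]],
                  if (is.finite(x$stderr[[p]]))
                    sprintf(" +/- %.3g", x$stderr[[p]]) else ""))
  if (isTRUE(x$one_sided))
    cat("  note: data lie on one side of the midpoint; errors are wide\n")
  invisible(x)
}

#' @export
coef.curve_fit <- function(object, ...) object$estimate

#' Convert tail-current amplitudes to fractional block
#'
#' Fractional block relative to the drug-free baseline,
#' \eqn{1 - I/I_{baseline}}.
#'
#' @param current Current amplitudes in the presence of drug.
#' @param baseline Drug-free amplitude (same units).
#' @return Fractional block.
#' @export
block_from_current <- function(current, baseline) {
  stopifnot(all(baseline > 0))
  1 - current / baseline
}

#' Compare a fitted parameter across recording conditions
#'
#' Welch-style two-sample t test on per-cell parameter estimates, one
#' planned comparison per parameter (no multiple-testing correction).
#'
#' @param results Named list (one element per condition label) of either
#'   numeric vectors of per-cell estimates or lists of `curve_fit` objects.
#' @param parameter Parameter name to extract from `curve_fit` elements.
#' @return Data frame with one row per condition pair: the two labels,
#'   group means and sizes, `difference` (first minus second), `stderr`,
#'   `t`, `df` (Welch-Satterthwaite), and two-sided `p`.
#' @export
compare_conditions <- function(results, parameter = NULL) {
  stopifnot(is.list(results), length(results) >= 2L,
            !is.null(names(results)))
  values <- lapply(results, function(grp) {
    if (is.numeric(grp)) return(as.numeric(grp))
    vapply(grp, function(f) {
      stopifnot(inherits(f, "curve_fit"))
      f$estimate[[parameter]]
    }, 0)
  })
  bad <- names(values)[vapply(values, length, 0L) < 2L]
  if (length(bad) > 0L)
    stop("need at least 2 per-cell fits per condition; too few in: ",
         paste(bad, collapse = ", "))
  labs <- names(values)
  pairs <- utils::combn(labs, 2L, simplify = FALSE)
  out <- lapply(pairs, function(pr) {
    x <- values[[pr[1]]]; y <- values[[pr[2]]]
    d <- mean(x) - mean(y)
    vx <- stats::var(x) / length(x); vy <- stats::var(y) / length(y)
    se <- sqrt(vx + vy)
    if (se == 0) {
      tval <- 0; df <- length(x) + length(y) - 2; p <- 1
    } else {
      tval <- d / se
      df <- (vx + vy)^2 / (vx^2 / (length(x) - 1) + vy^2 / (length(y) - 1))
      p <- 2 * stats::pt(-abs(tval), df)
    }
    data.frame(condition_a = pr[1], condition_b = pr[2],
               mean_a = mean(x), mean_b = mean(y),
               n_a = length(x), n_b = length(y),
               difference = d, stderr = se, t = tval, df = df, p = p)
  })
  do.call(rbind, out)
}
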