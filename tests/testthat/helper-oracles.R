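# Independent reference implementations used as oracles. These are written
# directly from the defining equations with plain loops and no acceleration,
# deliberately sharing no code with the package internals they check.

# Direct fixed-point iteration of the WHAM equations on histogram counts.
# counts: W x M matrix; mids: bin centres; centers, ks: window restraints.
# Returns the per-window free-energy constants with f[1] = 0.
wham_reference_f <- function(counts, mids, centers, ks, kT, half = 0.5,
                             tol = 1e-10, max_iter = 2e5) {
  W <- nrow(counts); M <- ncol(counts)
  N <- rowSums(counts)
  bias <- matrix(0, W, M)
  for (i in 1:W)
    for (m in 1:M)
      bias[i, m] <- half * ks[i] * (mids[m] - centers[i])^2
  f <- rep(0, W)
  for (it in 1:max_iter) {
    rho <- numeric(M)
    for (m in 1:M) {
      den <- 0
      for (i in 1:W) den <- den + N[i] * exp((f[i] - bias[i, m]) / kT)
      tot <- sum(counts[, m])
      rho[m] <- if (den > 0 && tot > 0) tot / den else 0
    }
    fnew <- numeric(W)
    for (i in 1:W) {
      s <- 0
      for (m in 1:M) s <- s + rho[m] * exp(-bias[i, m] / kT)
      fnew[i] <- -kT * log(s)
    }
    fnew <- fnew - fnew[1]
    if (max(abs(fnew - f)) <= tol) return(fnew)
    f <- fnew
  }
  f
}

# Analytic biased density for a flat true potential: the biased Boltzmann
# law is exactly Gaussian with sd = sqrt(kT / (2 * half * k)).
flat_biased_sd <- function(k, kT, half = 0.5) sqrt(kT / (2 * half * k))

# Deterministic "perfect-sampling" histogram counts: expected counts of the
# analytic biased density of a flat potential, rounded.
flat_analytic_counts <- function(n, breaks, center, k, kT, half = 0.5) {
  s <- flat_biased_sd(k, kT, half)
  p <- diff(pnorm(breaks, mean = center, sd = s))
  round(n * p / sum(p))
}

# Build an umbrella_series by hand (bypasses the package sampler), e.g. for
# i.i.d. draws from the analytic biased law.
manual_series <- function(samples, center, k, bias_half = TRUE) {
  structure(list(samples = samples, sample_interval = 1L, seed = NA_integer_,
                 window = list(center = center, k = k,
                               bias_half = bias_half)),
            class = "umbrella_series")
}

# Closed-form algebraic Hill solve from two exact points:
# block(ic50) = 1/2 fixes ic50; block at 10*ic50 fixes n_h.
hill_two_point_solution <- function(c_mid, block_at_10x) {
  list(ic50 = c_mid, n_h = -log10(1 / block_at_10x - 1))
}

# Power of the Welch t test by normal-approximation-free brute force is the
# package's own job to match; the analytic oracle uses the noncentral t with
# Welch-Satterthwaite df computed from the true variances.
welch_power_oracle <- function(m1, m2, sd1, sd2, n1, n2, alpha = 0.05) {
  v1 <- sd1^2 / n1; v2 <- sd2^2 / n2
  df <- (v1 + v2)^2 / (v1^2 / (n1 - 1) + v2^2 / (n2 - 1))
  ncp <- (m1 - m2) / sqrt(v1 + v2)
  tc <- qt(1 - alpha / 2, df)
  pt(-tc, df, ncp) + 1 - pt(tc, df, ncp)
}

# RMS deviation between a recovered PMF and the analytic truth after
# aligning their means over the shared supported bins.
pmf_rms_vs_truth <- function(pmf, potential) {
  sup <- !is.na(pmf$w)
  tw <- potential$fn(pmf$z[sup])
  dev <- (pmf$w[sup] - tw)
  dev <- dev - mean(dev)
  sqrt(mean(dev^2))
}
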