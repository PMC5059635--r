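test_that("Hill fits recover generating parameters and closed forms", {
  cc <- 10^seq(log10(0.002), log10(0.5), length.out = 6)
  fit <- fit_hill(generate_hill_data(0.015, 4.2, cc))
  expect_true(fit$converged)
  expect_equal(unname(coef(fit)[["ic50"]]), 0.015, tolerance = 1e-7)
  expect_equal(unname(coef(fit)[["n_h"]]), 4.2, tolerance = 1e-7)

  # exact points at c = IC50 (block 1/2) and c = 10 IC50 pin the algebraic
  # solution n_h = -log10(1/b10 - 1); the least-squares fit must match it
  ic50 <- 0.08; n_true <- 1.7
  c3 <- c(ic50 / 10, ic50, 10 * ic50)
  d <- generate_hill_data(ic50, n_true, c3)
  alg <- hill_two_point_solution(ic50, d$block_fraction[3])
  expect_equal(alg$n_h, n_true, tolerance = 1e-12)
  fit2 <- fit_hill(d)
  expect_equal(unname(coef(fit2)[["ic50"]]), alg$ic50, tolerance = 1e-6)
  expect_equal(unname(coef(fit2)[["n_h"]]), alg$n_h, tolerance = 1e-6)
})

test_that("degenerate or malformed dose-response tables are refused", {
  cc <- c(0.01, 0.1, 1)
  flatd <- data.frame(concentration_uM = cc, block_fraction = 0.5)
  expect_error(fit_hill(flatd), "degenerate")
  expect_error(fit_hill(data.frame(concentration_uM = c(1, 2),
                                   block_fraction = c(0.2, 0.8))),
               "3 distinct")
  expect_error(fit_hill(data.frame(concentration_uM = cc,
                                   block_fraction = c(0.2, 0.8, 1.4))),
               "\\[0, 1\\]")
  expect_error(fit_hill(data.frame(conc = cc, block = c(0.1, 0.5, 0.9))),
               "concentration_uM")
})

test_that("exponential fits recover tau, amplitude and offset", {
  d <- generate_exponential_block(5, seq(0, 25, 1))
  fit <- fit_exponential(d)
  expect_true(fit$converged)
  expect_equal(unname(coef(fit)[["tau"]]), 5, tolerance = 1e-7)
  expect_equal(unname(coef(fit)[["A"]]), 1, tolerance = 1e-6)
  expect_equal(unname(coef(fit)[["C"]]), 0, tolerance = 1e-6)

  # time-rescaling equivariance: t -> 2t doubles tau
  d2 <- d; d2$time_s <- d$time_s * 2
  expect_equal(unname(coef(fit_exponential(d2))[["tau"]]), 10,
               tolerance = 1e-6)

  # without-offset variant is recorded in the model name
  fit_noC <- fit_exponential(d, offset = FALSE)
  expect_identical(fit_noC$model, "exponential")
  expect_equal(unname(coef(fit_noC)[["tau"]]), 5, tolerance = 1e-7)
})

test_that("non-decaying or constant time courses are flagged or refused", {
  expect_error(fit_exponential(data.frame(time_s = 0:5,
                                          i_norm = rep(1, 6))),
               "constant")
  rising <- data.frame(time_s = 0:10, i_norm = seq(0.1, 1, length.out = 11))
  fit <- fit_exponential(rising)
  expect_false(fit$converged)
})

test_that("Boltzmann fits recover V1/2 and slope with equivariances", {
  vv <- seq(-50, 50, 10)
  fit <- fit_boltzmann(generate_gv_data(3.7, 8.2, vv))
  expect_true(fit$converged)
  expect_equal(unname(coef(fit)[["v_half"]]), 3.7, tolerance = 1e-6)
  expect_equal(unname(coef(fit)[["slope"]]), 8.2, tolerance = 1e-7)

  # midpoint identity: the fitted curve passes through 0.5 at V1/2
  vh <- coef(fit)[["v_half"]]; sl <- coef(fit)[["slope"]]
  expect_equal(1 / (1 + exp((vh - vh) / sl)), 0.5)

  # translation equivariance: V + 10 shifts V1/2 by 10, slope unchanged
  d <- generate_gv_data(-2.5, 9.2, vv)
  d10 <- d; d10$voltage_mV <- d$voltage_mV + 10
  f0 <- fit_boltzmann(d); f10 <- fit_boltzmann(d10)
  expect_equal(coef(f10)[["v_half"]] - coef(f0)[["v_half"]], 10,
               tolerance = 1e-6)
  expect_equal(coef(f10)[["slope"]], coef(f0)[["slope"]], tolerance = 1e-6)

  # one-sided data are flagged, not refused
  one_sided <- fit_boltzmann(generate_gv_data(-40, 8, seq(-20, 40, 10)))
  expect_true(one_sided$one_sided)
})

test_that("fits are invariant to row order and deterministic", {
  cc <- 10^seq(-2.5, 0, length.out = 8)
  d <- generate_hill_data(0.07, 2.1, cc, noise_sd = 0.03, seed = 12)
  shuffled <- d[sample.int(nrow(d)), ]
  f1 <- fit_hill(d); f2 <- fit_hill(shuffled)
  expect_identical(coef(f1), coef(f2))
  expect_identical(f1$rss, f2$rss)
})

test_that("fractional block adapter inverts tail-current amplitudes", {
  expect_equal(block_from_current(c(100, 50, 0), 100), c(0, 0.5, 1))
})

test_that("condition comparisons behave like a Welch t test", {
  a <- c(1.2, 0.8, 1.1, 0.9)
  cmp_same <- compare_conditions(list(ctrl = a, acid = a))
  expect_equal(cmp_same$difference, 0)
  expect_equal(cmp_same$p, 1)

  b <- c(2.4, 2.2, 2.9, 2.6, 2.1)
  cmp <- compare_conditions(list(ctrl = a, acid = b))
  flipped <- compare_conditions(list(acid = b, ctrl = a))
  expect_equal(cmp$difference, -flipped$difference)
  expect_equal(cmp$p, flipped$p)
  ref <- t.test(a, b)
  expect_equal(cmp$p, ref$p.value, tolerance = 1e-12)
  expect_equal(cmp$t, unname(ref$statistic), tolerance = 1e-12)

  expect_error(compare_conditions(list(a = 1, b = c(1, 2))), "at least 2")
})

test_that("rejection frequency matches the analytic Welch power", {
  # midpoint-shift design: two groups of per-cell V1/2 estimates
  m1 <- -2.5; m2 <- 3.7; s1 <- 1.9 * sqrt(5); s2 <- 2.2 * 2
  n1 <- 5; n2 <- 4
  set.seed(314)
  rej <- mean(replicate(400, {
    cmp <- compare_conditions(list(a = rnorm(n1, m1, s1),
                                   b = rnorm(n2, m2, s2)))
    cmp$p < 0.05
  }))
  expect_equal(rej, welch_power_oracle(m1, m2, s1, s2, n1, n2),
               tolerance = 0.08)
})

test_that("IC50 estimates are nearly unbiased at realistic design points", {
  # 5 half-log concentrations, 5% measurement noise, 300 replicates
  cc <- 10^seq(log10(0.004), log10(0.4), length.out = 5)
  est <- vapply(seq_len(300), function(s) {
    d <- generate_hill_data(0.041, 2.4, cc, noise_sd = 0.05, seed = s)
    start_c <- cc[which.min(abs(d$block_fraction - 0.5))]
    fit <- fit_hill(d, start = list(ic50 = start_c, n_h = 2))
    if (fit$converged) coef(fit)[["ic50"]] else NA_real_
  }, 0)
  est <- est[is.finite(est)]
  expect_gt(length(est), 280)
  expect_lt(abs(mean(est) / 0.041 - 1), 0.05)
})
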