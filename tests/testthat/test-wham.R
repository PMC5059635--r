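kT310 <- pmfbind::kBT(310.15)

test_that("a single unbiased window with uniform counts gives a flat PMF", {
  s <- manual_series(rep(seq(0.05, 0.95, 0.1), each = 10), 0, 1e-12)
  h <- build_histograms(list(s), bin_width = 0.1, burn_in_fraction = 0,
                        range = c(0, 1))
  sol <- solve_wham(h)
  expect_true(sol$converged)
  pmf <- pmf_from_solution(sol)
  expect_lt(diff(range(pmf$w)), 1e-10)
})

test_that("analytic-count flat-potential histograms reconstruct a flat PMF", {
  # two overlapping windows whose counts are the expected counts of the
  # exact biased Gaussians of a flat true potential
  breaks <- seq(-1.5, 1.5, 0.1)
  n <- 1e5
  counts <- rbind(
    flat_analytic_counts(n, breaks, -0.25, 10, kT310),
    flat_analytic_counts(n, breaks, 0.25, 10, kT310))
  h <- build_histograms(
    list(manual_series(rep(-0.25, 10), -0.25, 10),
         manual_series(rep(0.25, 10), 0.25, 10)),
    bin_width = 0.1, burn_in_fraction = 0, range = c(-1.5, 1.5))
  h$counts <- counts
  h$n_total <- rowSums(counts)
  sol <- solve_wham(h)
  expect_true(sol$converged)
  pmf <- pmf_from_solution(sol)
  core <- !is.na(pmf$w) & abs(pmf$z) < 1 # bins with meaningful support
  expect_lt(diff(range(pmf$w[core])), 0.05)
})

test_that("converged constants match the independent fixed-point oracle", {
  # <= 5-window instances, agreement to 1e-6 kcal/mol
  pot <- preset_potential("open-like")
  lay <- make_window_layout(-18, -16, 0.5, 10)
  ser <- simulate_windows(pot, lay, sampler_params(n_steps = 5000), seed = 13)
  h <- build_histograms(ser)
  sol <- solve_wham(h, tolerance = 1e-10)
  expect_true(sol$converged)
  f_ref <- wham_reference_f(h$counts, h$mids, h$windows$center,
                            h$windows$k, kT310, tol = 1e-12)
  expect_lt(max(abs(sol$f - f_ref)), 1e-6)

  # and with the accelerated path disabled the same fixed point is reached
  sol_plain <- solve_wham(h, tolerance = 1e-10, anderson = FALSE,
                          max_iter = 5e4)
  expect_lt(max(abs(sol_plain$f - f_ref)), 1e-6)
})

test_that("solution is invariant to duplicating every sample", {
  pot <- preset_potential("flat", domain = c(-2, 2))
  lay <- make_window_layout(-0.5, 0.5, 0.5, 10)
  ser <- simulate_windows(pot, lay, sampler_params(n_steps = 2000), seed = 5)
  h <- build_histograms(ser, burn_in_fraction = 0)
  h2 <- h
  h2$counts <- h$counts * 2L
  h2$n_total <- h$n_total * 2L
  s1 <- solve_wham(h, tolerance = 1e-9)
  s2 <- solve_wham(h2, tolerance = 1e-9)
  expect_equal(s1$f, s2$f, tolerance = 1e-7)
})

test_that("reported residual obeys the tolerance semantics", {
  pot <- preset_potential("open-like")
  lay <- make_window_layout(-12, -10, 0.5, 10)
  ser <- simulate_windows(pot, lay, sampler_params(n_steps = 3000), seed = 1)
  h <- build_histograms(ser)
  sol <- solve_wham(h, tolerance = 1e-7)
  expect_true(sol$converged)
  expect_lte(sol$residual, 1e-7)
  expect_equal(sol$f[1], 0)

  capped <- solve_wham(h, tolerance = 1e-12, max_iter = 2, anderson = FALSE)
  expect_false(capped$converged)
  expect_error(pmf_from_solution(capped), "not converged")
  expect_s3_class(pmf_from_solution(capped, allow_unconverged = TRUE),
                  "pmf_profile")
})

test_that("disconnected window sets are refused with their components", {
  a <- manual_series(rnorm(500, -5, 0.1), -5, 10)
  b <- manual_series(rnorm(500, 5, 0.1), 5, 10)
  h <- build_histograms(list(a, b), bin_width = 0.1, burn_in_fraction = 0,
                        range = c(-6, 6))
  expect_error(solve_wham(h), "connected")
})

test_that("PMF error shrinks as sampling grows (perfect-sampling limit)", {
  pot <- preset_potential("open-like")
  lay <- make_window_layout(-20, -8, 0.5, 10)
  rms_at_n <- function(n, seed) {
    ser <- simulate_windows(pot, lay, sampler_params(n_steps = n),
                            seed = seed)
    sol <- solve_wham(build_histograms(ser))
    pmf_rms_vs_truth(pmf_from_solution(sol, allow_unconverged = TRUE), pot)
  }
  rms <- sapply(c(1e3, 1e4, 1e5), function(n)
    mean(sapply(c(101, 202), function(sd) rms_at_n(n, sd))))
  expect_true(all(diff(rms) < 0))
})

test_that("full open-pore synthetic run recovers the preset PMF", {
  pot <- preset_potential("open-like")
  lay <- make_window_layout(-49.5, -7.5, 0.5, 10)
  ser <- simulate_windows(pot, lay, sampler_params(n_steps = 5e4), seed = 17)
  sol <- solve_wham(build_histograms(ser))
  expect_true(sol$converged)
  pmf <- pmf_from_solution(sol)
  expect_lt(pmf_rms_vs_truth(pmf, pot), 0.2)
})

test_that("PMF extraction obeys its defining identities", {
  mids <- seq(0.05, 0.95, 0.1)
  s <- manual_series(mids, 0, 1e-12)
  h <- build_histograms(list(s), bin_width = 0.1, burn_in_fraction = 0,
                        range = c(0, 1))
  sol <- solve_wham(h)
  # density ratio e between two bins -> w difference of exactly kT
  sol$density <- rep(1, length(mids))
  sol$density[3] <- exp(1)
  sol$support <- rep(TRUE, length(mids))
  pmf <- pmf_from_solution(sol)
  expect_equal(pmf$w[1] - pmf$w[3], kT310, tolerance = 1e-12)
  # doubling all densities shifts w by a constant only
  sol2 <- sol
  sol2$density <- sol$density * 2
  pmf2 <- pmf_from_solution(sol2)
  expect_equal(diff(range((pmf2$w - pmf$w))), 0, tolerance = 1e-12)
  # zero-count bins come out missing, not zero
  sol3 <- sol
  sol3$support[5] <- FALSE
  sol3$density[5] <- 0
  pmf3 <- pmf_from_solution(sol3)
  expect_true(is.na(pmf3$w[5]))
  expect_equal(pmf3$w[-5], pmf$w[-5])
})

test_that("bulk anchoring zeroes the bulk mean and is shift-invariant", {
  z <- seq(-20.05, -5.05, 0.1)
  w <- sin(z / 3) + 5
  pmf <- pmf_profile(z, w)
  anchored <- offset_to_bulk(pmf, c(-20, -17))
  sel <- anchored$z >= -20 & anchored$z <= -17
  expect_equal(mean(anchored$w[sel]), 0, tolerance = 1e-12)
  expect_identical(attr(anchored, "offset"), "bulk-zero")
  # offset invariance: pmf + c anchors to the identical profile
  shifted <- pmf_profile(z, w + 123.4)
  expect_equal(offset_to_bulk(shifted, c(-20, -17))$w, anchored$w,
               tolerance = 1e-10)
  # flat profile at 5 anchors to flat 0
  flat <- offset_to_bulk(pmf_profile(z, rep(5, length(z))), c(-20, -17))
  expect_true(all(flat$w == 0))
  # insufficient bulk support is an error
  expect_error(offset_to_bulk(pmf, c(-4, -3)), "fewer than 3")
})

test_that("anchored synthetic PMF recovers the preset well depth", {
  pot <- preset_potential("inactivated-like")
  lay <- make_window_layout(-38, -8.5, 0.5, 10)
  ser <- simulate_windows(pot, lay, sampler_params(n_steps = 2e4), seed = 23)
  sol <- solve_wham(build_histograms(ser))
  pmf <- offset_to_bulk(pmf_from_solution(sol, allow_unconverged = TRUE),
                        c(-38, -35))
  expect_equal(min(pmf$w, na.rm = TRUE), -18, tolerance = 0.15)
})
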