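params310 <- thermo_params()

flat_site_pmf <- function() {
  pmf_profile(z = seq(-14.95, -5.05, 0.1), w = rep(0, 100),
              offset = "bulk-zero", bulk_range = c(-14.95, -12))
}

test_that("a flat 10-Angstrom site at R = 10 gives K_D = 0.5286 M", {
  kd <- kd_from_pmf(flat_site_pmf(), params310, site_bounds = c(-15, -5))
  # closed form: 1 / (pi R^2 N_A 1e-27 * 10 A)
  expect_equal(as.numeric(kd),
               1 / (pi * 100 * 6.02214076e23 * 1e-27 * 10),
               tolerance = 1e-12)
  expect_equal(as.numeric(kd), 0.5286, tolerance = 1e-4)
  expect_equal(attr(kd, "site_bounds"), c(-15, -5))
})

test_that("the square-well closed form gives K_D = 1.584e-3 M", {
  sq <- preset_potential("square-well", depth = -5, width = 1)
  kd <- true_kd(sq, params310, c(-0.5, 0.5))
  expect_equal(kd, exp(-5 / kBT(params310)) /
                 (pi * 100 * 6.02214076e23 * 1e-27),
               tolerance = 1e-9)
  expect_equal(kd, 1.584e-3, tolerance = 1e-3)
})

test_that("grid quadrature of a smooth PMF matches adaptive quadrature", {
  # trapezoid on the 0.1-A bin grid vs integrate() on the analytic curve,
  # and a Richardson-style check that halving the grid step changes little
  pot <- preset_potential("open-like")
  mk <- function(dz) {
    z <- seq(-40 + dz / 2, -7.5 - dz / 2, dz)
    pmf_profile(z, pot$fn(z), offset = "bulk-zero",
                bulk_range = c(-40, -35))
  }
  bounds <- c(-20, -8)
  kd_ref <- true_kd(pot, params310, bounds)
  kd_coarse <- as.numeric(kd_from_pmf(mk(0.1), params310, bounds))
  kd_fine <- as.numeric(kd_from_pmf(mk(0.05), params310, bounds))
  expect_equal(kd_coarse, kd_ref, tolerance = 2e-3)
  expect_lt(abs(kd_fine - kd_ref), abs(kd_coarse - kd_ref))
})

test_that("K_D scales as 1/R^2 and responds monotonically to the PMF", {
  pmf <- flat_site_pmf()
  kd10 <- as.numeric(kd_from_pmf(pmf, thermo_params(cylinder_radius = 10),
                                 c(-15, -5)))
  kd5 <- as.numeric(kd_from_pmf(pmf, thermo_params(cylinder_radius = 5),
                                c(-15, -5)))
  expect_equal(kd5 / kd10, 4, tolerance = 1e-12)

  # deepening w anywhere in the site strictly decreases K_D
  deeper <- pmf
  deeper$w[50] <- -1
  expect_lt(as.numeric(kd_from_pmf(deeper, params310, c(-15, -5))), kd10)
  # widening the site never increases K_D
  wide <- pmf_profile(z = seq(-16.95, -5.05, 0.1), w = rep(0, 120),
                      offset = "bulk-zero")
  expect_lte(as.numeric(kd_from_pmf(wide, params310, c(-16, -5))),
             as.numeric(kd_from_pmf(wide, params310, c(-15, -5))))
})

test_that("raw-offset or unsupported-site profiles are refused", {
  raw <- pmf_profile(z = seq(-10, -5, 0.1), w = rep(0, 51), offset = "raw")
  expect_error(kd_from_pmf(raw, params310, c(-9, -6)), "offset_to_bulk")
  holey <- flat_site_pmf()
  holey$w[50] <- NA
  expect_error(kd_from_pmf(holey, params310, c(-15, -5)), "unsupported")
})

test_that("Delta G and K_D interconvert exactly (standard-state identity)", {
  expect_equal(dg_from_kd(1, params310), 0)
  expect_equal(kd_from_dg(0, params310), 1)
  for (kd in c(1.32e-3, 6.7e-8, 1.32e-9, 3.22e-12)) {
    expect_equal(kd_from_dg(dg_from_kd(kd, params310), params310), kd,
                 tolerance = 1e-12)
  }
  expect_equal(kd_from_dg(-16.30, params310), 3.26e-12, tolerance = 1e-2)
  expect_error(dg_from_kd(-1), "kd > 0")
})

test_that("published-scale K_D values give the published free energies", {
  # four dissociation constants spanning mM to pM reproduce their
  # tabulated free energies within the 3-significant-figure rounding
  kds <- c(1.32e-9, 6.70e-8, 1.32e-3, 3.22e-12)
  dgs <- c(-12.59, -10.18, -4.09, -16.30)
  expect_true(all(abs(dg_from_kd(kds, params310) - dgs) <= 0.02))
})

test_that("binding results are internally consistent and comparable", {
  open_n <- binding_result(kd = 1.32e-9, params = params310,
                           label = "neutral/open")
  inact_n <- binding_result(kd = 6.70e-8, params = params310,
                            label = "neutral/inactivated")
  expect_equal(open_n$dg, dg_from_kd(open_n$kd, params310))
  dd <- delta_delta_g(open_n, inact_n)
  expect_equal(dd$ddg, dg_from_kd(1.32e-9) - dg_from_kd(6.70e-8))
  expect_true(is.na(dd$stderr))
  expect_equal(delta_delta_g(open_n, open_n)$ddg, 0)
  other <- binding_result(kd = 1e-9, params = thermo_params(300))
  expect_error(delta_delta_g(open_n, other), "different thermodynamic")
})

test_that("protonated fraction follows Henderson-Hasselbalch", {
  expect_equal(protonated_fraction(7.0, 7.0), 0.5)
  expect_equal(protonated_fraction(7.4, 7.0), 1 / (1 + 10^0.4))
  expect_equal(protonated_fraction(6.2, 7.0), 1 / (1 + 10^-0.8))
  # strictly decreasing in pH
  ph <- seq(4, 10, 0.25)
  expect_true(all(diff(protonated_fraction(ph, 7.0)) < 0))
})

test_that("error propagation through the site integral behaves linearly", {
  z <- seq(-14.95, -5.05, 0.1)
  well <- -3 * exp(-(z + 10)^2 / 2)
  mk <- function(se) pmf_profile(z, well, stderr = se,
                                 offset = "bulk-zero")
  # zero stderr everywhere propagates to exactly zero
  expect_identical(propagate_dg_error(mk(0), params310, c(-14, -6),
                                      n_boot = 50, seed = 2), 0)
  # fixed seed gives reproducible errors
  e1 <- propagate_dg_error(mk(0.05), params310, c(-14, -6),
                           n_boot = 200, seed = 2)
  e2 <- propagate_dg_error(mk(0.05), params310, c(-14, -6),
                           n_boot = 200, seed = 2)
  expect_identical(e1, e2)
  expect_gt(e1, 0)
  # small-error linearization: doubling per-bin errors ~doubles stderr_dG
  e_dbl <- propagate_dg_error(mk(0.10), params310, c(-14, -6),
                              n_boot = 200, seed = 2)
  expect_equal(e_dbl / e1, 2, tolerance = 0.15)
  # missing errors on site bins are refused
  holey <- mk(0.05); holey$stderr[50] <- NA
  expect_error(propagate_dg_error(holey, params310, c(-14, -6),
                                  n_boot = 50, seed = 1), "missing")
})

test_that("binding result from a PMF with errors carries stderr_dG", {
  z <- seq(-20.05, -5.05, 0.1)
  w <- -6 * exp(-(z + 10)^2 / 2)
  pmf <- pmf_profile(z, w, stderr = 0.05, offset = "bulk-zero",
                     bulk_range = c(-20, -17))
  res <- binding_result(pmf, params310, seed = 3)
  expect_true(is.finite(res$stderr_dg) && res$stderr_dg > 0)
  expect_equal(res$dg, dg_from_kd(res$kd, params310))
  expect_true(res$site_bounds[1] <= -10 && res$site_bounds[2] >= -10)
  # auto bounds walk from the well toward bulk until w > -kT
  expect_lt(max(abs(res$site_bounds -
                      auto_site_bounds(pmf, params310))), 1e-9)
})
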