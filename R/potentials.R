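#' Construct an analytic ground-truth potential
#'
#' A `true_potential` is an analytic 1-D free-energy profile u(z) used by the
#' synthetic-data module as the known truth behind generated umbrella-window
#' trajectories. z is the position of the ligand centre of mass along the
#' pore axis relative to the selectivity-filter anchor; more negative z is
#' deeper toward the intracellular gate, and the bulk (aqueous) region sits
#' at the most negative end of the domain.
#'
#' @param name Label for the potential.
#' @param fn Vectorized function of z (Angstrom) returning energy in
#'   kcal/mol. Must be finite on the domain.
#' @param domain Length-2 numeric, `c(z_lo, z_hi)` in Angstrom.
#' @param bulk Length-2 numeric giving the declared bulk region where
#'   u ~ 0, or `NULL` when the potential has no bulk plateau.
#' @param params Named list of shape parameters (depths, centers, widths),
#'   kept for documentation of provenance.
#' @return An object of class `true_potential`.
#' @seealso [preset_potential()] for the ready-made shapes.
#' @export
true_potential <- function(name, fn, domain, bulk = NULL, params = list()) {
  stopifnot(is.function(fn), is.numeric(domain), length(domain) == 2L,
            domain[1] < domain[2])
  if (!is.null(bulk)) {
    stopifnot(is.numeric(bulk), length(bulk) == 2L, bulk[1] < bulk[2],
              bulk[1] >= domain[1] - 1e-9, bulk[2] <= domain[2] + 1e-9)
  }
  zz <- seq(domain[1], domain[2], length.out = 501L)
  if (!all(is.finite(fn(zz))))
    stop("potential is not finite everywhere on its domain")
  structure(list(name = name, fn = fn, domain = domain, bulk = bulk,
                 params = params),
            class = "true_potential")
}

gauss_well <- function(z, depth, center, width) {
  depth * exp(-(z - center)^2 / (2 * width^2))
}

#' Preset ground-truth potentials
#'
#' Ready-made analytic potentials emulating the qualitative PMF shapes seen
#' for drug block of a K+ channel pore:
#' \describe{
#'   \item{`"open-like"`}{Two separated wells of about -8 and -7 kcal/mol
#'     (two tentative intra-cavity binding sites of an open pore) plus a
#'     repulsive wall toward the selectivity filter; zero in bulk.}
#'   \item{`"inactivated-like"`}{One deep well of -18 kcal/mol (lock-in
#'     binding to an inactivated pore) plus a shallow outer minimum near the
#'     gate; zero in bulk.}
#'   \item{`"flat"`}{u(z) = 0 everywhere.}
#'   \item{`"harmonic"`}{u(z) = (k/2)(z - center)^2; no bulk plateau.}
#'   \item{`"square-well"`}{u = depth inside a window of the given width
#'     centred at `center`, 0 outside; handy because its dissociation
#'     constant has a closed form.}
#' }
#'
#' @param name One of `"open-like"`, `"inactivated-like"`, `"flat"`,
#'   `"harmonic"`, `"square-well"`.
#' @param depth,width,center,k Shape parameters for the simple presets
#'   (kcal/mol, Angstrom, Angstrom, kcal mol^-1 A^-2).
#' @param domain Optional domain override, `c(z_lo, z_hi)` Angstrom.
#' @return A [true_potential()].
#' @examples
#' pot <- preset_potential("inactivated-like")
#' min(pot$fn(seq(pot$domain[1], pot$domain[2], 0.01))) # ~ -18 kcal/mol
#' @export
preset_potential <- function(name, depth = -5, width = 1, center = 0, k = 1,
                             domain = NULL) {
  presets <- c("open-like", "inactivated-like", "flat", "harmonic",
               "square-well")
  if (!is.character(name) || length(name) != 1L || !(name %in% presets))
    stop("unknown preset '", name, "'; available presets: ",
         paste(presets, collapse = ", "))
  switch(name,
    "open-like" = {
      dom <- if (is.null(domain)) c(-51, -6) else domain
      fn <- function(z) {
        gauss_well(z, -8, -16, 1.5) + gauss_well(z, -7, -10.5, 1.2) +
          ifelse(z > -8.5, 4 * (z + 8.5)^2, 0)
      }
      true_potential("open-like", fn, dom, bulk = c(dom[1], dom[1] + 5),
                     params = list(depths = c(-8, -7),
                                   centers = c(-16, -10.5),
                                   widths = c(1.5, 1.2),
                                   wall_at = -8.5, wall_k = 4))
    },
    "inactivated-like" = {
      dom <- if (is.null(domain)) c(-39.5, -7) else domain
      fn <- function(z) {
        gauss_well(z, -18, -10, 1.8) + gauss_well(z, -3, -16.5, 1.4) +
          ifelse(z > -9.5, 4 * (z + 9.5)^2, 0)
      }
      true_potential("inactivated-like", fn, dom,
                     bulk = c(dom[1], dom[1] + 5),
                     params = list(depths = c(-18, -3),
                                   centers = c(-10, -16.5),
                                   widths = c(1.8, 1.4),
                                   wall_at = -9.5, wall_k = 4))
    },
    "flat" = {
      dom <- if (is.null(domain)) c(-10, 10) else domain
      true_potential("flat", function(z) rep(0, length(z)), dom,
                     bulk = dom, params = list())
    },
    "harmonic" = {
      dom <- if (is.null(domain)) center + c(-6, 6) else domain
      force(k); force(center)
      true_potential("harmonic",
                     function(z) 0.5 * k * (z - center)^2, dom,
                     bulk = NULL, params = list(k = k, center = center))
    },
    "square-well" = {
      dom <- if (is.null(domain)) center + c(-8, 8) else domain
      force(depth); force(width); force(center)
      fn <- function(z) ifelse(abs(z - center) < width / 2, depth, 0)
      true_potential("square-well", fn, dom,
                     bulk = c(center + width / 2 + 0.5, dom[2]),
                     params = list(depth = depth, width = width,
                                   center = center))
    })
}

#' @export
print.true_potential <- function(x, ...) {
  cat(sprintf("True potential '%s' on [%.2f, %.2f] Angstrom\n",
              x$name, x$domain[1], x$domain[2]))
  if (!is.null(x$bulk))
    cat(sprintf("  bulk region: [%.2f, %.2f]\n", x$bulk[1], x$bulk[2]))
  zz <- seq(x$domain[1], x$domain[2], length.out = 2001L)
  cat(sprintf("  min u = %.3f kcal/mol at z = %.2f\n",
              min(x$fn(zz)), zz[which.min(x$fn(zz))]))
  invisible(x)
}

#' Closed-form dissociation constant of a ground-truth potential
#'
#' Reference value for end-to-end recovery checks: applies the cylindrical
#' restraint formula directly to the analytic u(z),
#' \deqn{K_D = \left[\pi R^2 N_A 10^{-27} \int_{site} e^{-u(z)/k_BT} dz\right]^{-1},}
#' with the integral evaluated by adaptive quadrature rather than on a
#' histogram grid.
#'
#' @param potential A [true_potential()].
#' @param params A [thermo_params()].
#' @param site_bounds `c(z_lo, z_hi)` of the bound-state region, Angstrom.
#' @return K_D in mol/L.
#' @export
true_kd <- function(potential, params = thermo_params(), site_bounds) {
  stopifnot(inherits(potential, "true_potential"),
            is.numeric(site_bounds), length(site_bounds) == 2L,
            site_bounds[1] < site_bounds[2])
  kT <- kBT(params)
  I <- stats::integrate(function(z) exp(-potential$fn(z) / kT),
                        site_bounds[1], site_bounds[2],
                        subdivisions = 2000L, rel.tol = 1e-10)$value
  vol <- pi * params$cylinder_radius^2 * I          # Angstrom^3
  1 / (vol * 1e-27 * params$N_A)                    # mol/L
}
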