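#' Lay out umbrella-sampling windows along the reaction coordinate
#'
#' Builds the ordered set of harmonic window restraints covering
#' `[z_min, z_max]` at a fixed spacing, each with the same force constant.
#' The range must be an integer multiple of the spacing (to 1e-9), so the
#' last centre lands exactly on `z_max`.
#'
#' @param z_min,z_max Range of window centres in Angstrom (`z_max >= z_min`).
#' @param spacing Distance between adjacent centres, Angstrom. Default 0.5.
#' @param k Harmonic force constant, kcal mol^-1 A^-2. Default 10.
#' @return A `window_layout`: a data frame with columns `center` (Angstrom)
#'   and `k`, one row per window, ordered by centre.
#' @examples
#' nrow(make_window_layout(-49.5, -7.5)) # 85 windows, open-pore layout
#' nrow(make_window_layout(-38.0, -8.5)) # 60 windows, open-inactivated
#' @export
make_window_layout <- function(z_min, z_max, spacing = 0.5, k = 10) {
  stopifnot(is.numeric(z_min), is.numeric(z_max), is.numeric(spacing),
            is.numeric(k))
  if (spacing <= 0) stop("window spacing must be > 0")
  if (k <= 0) stop("force constant must be > 0")
  if (z_max < z_min) stop("z_max must be >= z_min")
  n_real <- (z_max - z_min) / spacing
  n <- round(n_real)
  residual <- abs(n_real - n) * spacing
  if (residual > 1e-9)
    stop(sprintf(paste0("window range (%.6g to %.6g) is not a multiple of ",
                        "the spacing %.6g: residual %.3g Angstrom"),
                 z_min, z_max, spacing, residual))
  centers <- z_min + spacing * seq.int(0L, n)
  structure(data.frame(center = centers, k = k),
            class = c("window_layout", "data.frame"))
}

#' Total simulated time of an umbrella layout
#'
#' @param layout A [make_window_layout()] result.
#' @param per_window_ns Simulated time per window, ns.
#' @return Total time in microseconds.
#' @examples
#' layout_total_time_us(make_window_layout(-49.5, -7.5), 22) # 1.87 us
#' @export
layout_total_time_us <- function(layout, per_window_ns) {
  stopifnot(inherits(layout, "window_layout"), per_window_ns > 0)
  nrow(layout) * per_window_ns / 1000
}

#' Sampler parameters for synthetic umbrella trajectories
#'
#' Time is reduced (a dimensionless step index): only the relative amount of
#' sampling matters downstream, so one recorded sample stands in for one
#' saved MD frame. Defaults mirror a 22-ns window saved at 10 ps: 2.2e5
#' samples per window.
#'
#' @param n_steps Number of recorded samples per window.
#' @param dt Reduced time step.
#' @param D Diffusion coefficient, A^2 per reduced time. With `dt` it sets
#'   the proposal width `sqrt(2 D dt)`.
#' @param temperature Temperature in K.
#' @param scheme `"metropolis"` (random-walk Metropolis; exact biased
#'   Boltzmann stationary law, the default) or `"overdamped-langevin"`
#'   (uncorrected Euler-Maruyama; carries O(dt) discretization bias).
#' @param sample_interval Record every `sample_interval`-th step.
#' @param grid_dz Spacing of the grid on which the analytic potential is
#'   tabulated for the C++ kernel, Angstrom.
#' @param bias_half If `TRUE` (default) the window bias is
#'   U = (k/2)(z - z0)^2, the MD-engine convention; `FALSE` selects the
#'   k (z - z0)^2 dialect used by some WHAM tools.
#' @return An object of class `sampler_params`.
#' @export
sampler_params <- function(n_steps = 220000L, dt = 0.02, D = 1,
                           temperature = 310.15,
                           scheme = c("metropolis", "overdamped-langevin"),
                           sample_interval = 1L, grid_dz = 0.01,
                           bias_half = TRUE) {
  scheme <- match.arg(scheme)
  stopifnot(n_steps >= 1, dt > 0, D > 0, temperature > 0,
            sample_interval >= 1, grid_dz > 0, is.logical(bias_half))
  structure(list(n_steps = as.integer(n_steps), dt = dt, D = D,
                 temperature = temperature, scheme = scheme,
                 sample_interval = as.integer(sample_interval),
                 grid_dz = grid_dz, bias_half = bias_half),
            class = "sampler_params")
}

#' Sample a biased umbrella-window trajectory
#'
#' Draws a trajectory whose stationary distribution is the biased Boltzmann
#' law \eqn{\propto \exp\{-[u(z) + (k/2)(z-z_0)^2]/k_BT\}} for the window's
#' harmonic restraint (the 1/2 factor is dropped when
#' `params$bias_half = FALSE`). The default Metropolis scheme is exact for
#' the tabulated potential; the Langevin scheme is the usual Euler-Maruyama
#' discretization. Identical `(potential, window, params, seed)` give
#' bit-identical samples.
#'
#' @param potential A [true_potential()].
#' @param window One row of a [make_window_layout()] (or a list with
#'   `center` and `k`).
#' @param params A [sampler_params()].
#' @param seed Integer RNG seed (mandatory for reproducibility).
#' @return An `umbrella_series`: list with `samples` (numeric, Angstrom),
#'   `sample_interval`, `seed`, and `window`.
#' @examples
#' pot <- preset_potential("flat")
#' s <- sample_biased_trajectory(pot, list(center = 0, k = 10),
#'                               sampler_params(n_steps = 5000), seed = 1)
#' sd(s$samples) # ~ sqrt(kBT/k) = 0.248 Angstrom at 310.15 K
#' @export
sample_biased_trajectory <- function(potential, window,
                                     params = sampler_params(), seed) {
  stopifnot(inherits(potential, "true_potential"),
            inherits(params, "sampler_params"))
  if (missing(seed) || !is.numeric(seed))
    stop("an integer seed is required")
  center <- as.numeric(window$center)
  kwin <- as.numeric(window$k)
  stopifnot(length(center) == 1L, length(kwin) == 1L, kwin > 0)
  dom <- potential$domain
  if (center < dom[1] || center > dom[2])
    stop(sprintf("window center %.3f lies outside the potential domain [%g, %g]",
                 center, dom[1], dom[2]))
  zz <- seq(dom[1], dom[2], by = params$grid_dz)
  if (zz[length(zz)] < dom[2]) zz <- c(zz, dom[2])
  ugrid <- potential$fn(zz)
  kT <- kBT(params$temperature)
  half <- if (params$bias_half) 0.5 else 1.0
  # start at the minimum of the biased potential near the window centre
  ub <- ugrid + half * kwin * (zz - center)^2
  z0 <- zz[which.min(ub)]
  scheme_code <- if (params$scheme == "metropolis") 0L else 1L
  set.seed(as.integer(seed))
  samples <- .sampler_cpp(params$n_steps * params$sample_interval,
                          params$sample_interval, z0,
                          dom[1], zz[2] - zz[1], ugrid,
                          center, kwin, half, kT,
                          params$dt, params$D, scheme_code)
  structure(list(samples = samples,
                 sample_interval = params$sample_interval,
                 seed = as.integer(seed),
                 window = list(center = center, k = kwin,
                               bias_half = params$bias_half)),
            class = "umbrella_series")
}

#' @export
print.umbrella_series <- function(x, ...) {
  cat(sprintf(paste0("Umbrella trajectory: %d samples, window center %.2f ",
                     "Angstrom, k = %.3g kcal/(mol A^2), seed %d\n"),
              length(x$samples), x$window$center, x$window$k, x$seed))
  invisible(x)
}

#' Generate all window trajectories for a layout
#'
#' Per-window seeds are derived deterministically from the master seed, so
#' one master seed fixes the entire synthetic data set.
#'
#' @param potential A [true_potential()].
#' @param layout A [make_window_layout()].
#' @param params A [sampler_params()].
#' @param seed Master integer seed.
#' @return List of `umbrella_series`, one per window, in layout order.
#' @export
simulate_windows <- function(potential, layout, params = sampler_params(),
                             seed) {
  stopifnot(inherits(layout, "window_layout"))
  if (missing(seed)) stop("an integer master seed is required")
  set.seed(as.integer(seed))
  window_seeds <- sample.int(.Machine$integer.max, nrow(layout))
  lapply(seq_len(nrow(layout)), function(i) {
    sample_biased_trajectory(potential, layout[i, ], params,
                             seed = window_seeds[i])
  })
}
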