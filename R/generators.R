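#' Generate a noisy Hill concentration-response table
#'
#' Fractional block of the current follows the Hill equation
#' \eqn{b(c) = 1 / (1 + (IC_{50}/c)^{n_H})}; optional Gaussian noise is
#' added and the result clipped to \[0, 1\] (a fractional block cannot
#' leave that range).
#'
#' @param ic50 Half-maximal inhibitory concentration, uM.
#' @param n_h Hill coefficient (dimensionless, > 0).
#' @param concentrations Drug concentrations tested, uM.
#' @param noise_sd Standard deviation of additive Gaussian noise (fraction
#'   of full block). Default 0.
#' @param seed Integer seed; required when `noise_sd > 0`.
#' @return Data frame with columns `concentration_uM`, `block_fraction`.
#' @examples
#' generate_hill_data(0.041, 2.4, c(0.01, 0.03, 0.1, 0.3))
#' @export
generate_hill_data <- function(ic50, n_h, concentrations, noise_sd = 0,
                               seed = NULL) {
  stopifnot(ic50 > 0, n_h > 0, all(concentrations > 0), noise_sd >= 0)
  block <- 1 / (1 + (ic50 / concentrations)^n_h)
  block <- add_clipped_noise(block, noise_sd, seed, lo = 0, hi = 1)
  data.frame(concentration_uM = as.numeric(concentrations),
             block_fraction = block)
}

#' Generate a noisy single-exponential block time course
#'
#' Normalized current decays as \eqn{I(t) = e^{-t/\tau}} during
#' use-dependent block.
#'
#' @param tau Decay time constant, s.
#' @param times Sample times, s.
#' @param noise_sd Additive Gaussian noise SD. Default 0.
#' @param seed Integer seed; required when `noise_sd > 0`.
#' @return Data frame with columns `time_s`, `i_norm`.
#' @export
generate_exponential_block <- function(tau, times, noise_sd = 0,
                                       seed = NULL) {
  stopifnot(tau > 0, all(times >= 0), noise_sd >= 0)
  i <- exp(-times / tau)
  i <- add_clipped_noise(i, noise_sd, seed, lo = -Inf, hi = Inf)
  data.frame(time_s = as.numeric(times), i_norm = i)
}

#' Generate a noisy Boltzmann activation (g-V) table
#'
#' Normalized conductance follows
#' \eqn{g/g_{max} = 1 / (1 + \exp[(V_{1/2} - V)/k_s])}, the standard
#' activation curve with positive slope factor `k_s` meaning activation on
#' depolarization.
#'
#' @param v_half Half-activation voltage, mV.
#' @param slope Slope factor k_s, mV (nonzero).
#' @param voltages Test potentials, mV.
#' @param noise_sd Additive Gaussian noise SD. Default 0.
#' @param seed Integer seed; required when `noise_sd > 0`.
#' @return Data frame with columns `voltage_mV`, `g_norm`.
#' @export
generate_gv_data <- function(v_half, slope, voltages, noise_sd = 0,
                             seed = NULL) {
  stopifnot(is.numeric(v_half), slope != 0, noise_sd >= 0)
  g <- 1 / (1 + exp((v_half - voltages) / slope))
  g <- add_clipped_noise(g, noise_sd, seed, lo = -Inf, hi = Inf)
  data.frame(voltage_mV = as.numeric(voltages), g_norm = g)
}

add_clipped_noise <- function(y, noise_sd, seed, lo, hi) {
  if (noise_sd > 0) {
    if (is.null(seed)) stop("a seed is required when noise_sd > 0")
    set.seed(as.integer(seed))
    y <- y + stats::rnorm(length(y), 0, noise_sd)
  }
  pmin(pmax(y, lo), hi)
}
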