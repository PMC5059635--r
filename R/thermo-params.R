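#' Physical and geometric parameters for binding thermodynamics
#'
#' Bundles the constants entering the PMF-to-\eqn{K_D} conversion: the
#' temperature, Boltzmann constant, Avogadro number, the radius of the
#' flat-bottom cylindrical restraint that confines the ligand laterally,
#' and the standard concentration. The constants are pinned so results
#' are bit-reproducible across platforms, and every report echoes them.
#'
#' @param temperature Simulation temperature in K. Default 310.15 K
#'   (physiological).
#' @param cylinder_radius Radius R of the lateral flat-bottom cylindrical
#'   restraint, in Angstrom. Default 10.
#' @param standard_conc Standard concentration \eqn{c^0} in mol/L. Default 1.
#' @return An object of class `thermo_params`: a list with fields
#'   `temperature`, `kB` (kcal mol^-1 K^-1), `N_A` (mol^-1),
#'   `cylinder_radius` (Angstrom), `standard_conc` (mol/L).
#' @examples
#' p <- thermo_params()
#' kBT(p) # ~0.6163 kcal/mol at 310.15 K
#' @export
thermo_params <- function(temperature = 310.15, cylinder_radius = 10,
                          standard_conc = 1) {
  stopifnot(is.numeric(temperature), length(temperature) == 1L, temperature > 0,
            is.numeric(cylinder_radius), length(cylinder_radius) == 1L,
            cylinder_radius > 0,
            is.numeric(standard_conc), length(standard_conc) == 1L,
            standard_conc > 0)
  structure(list(
    temperature = temperature,
    kB = 1.9872041e-3,       # kcal mol^-1 K^-1
    N_A = 6.02214076e23,     # mol^-1
    cylinder_radius = cylinder_radius,
    standard_conc = standard_conc
  ), class = "thermo_params")
}

#' Thermal energy k_B * T
#'
#' @param params A [thermo_params()] object, or a temperature in K.
#' @return Thermal energy in kcal/mol.
#' @export
kBT <- function(params) {
  if (inherits(params, "thermo_params"))
    return(params$kB * params$temperature)
  stopifnot(is.numeric(params), params > 0)
  1.9872041e-3 * params
}

#' @export
print.thermo_params <- function(x, ...) {
  cat("Thermodynamic parameters\n")
  cat(sprintf("  T            = %.4g K   (k_B T = %.4f kcal/mol)\n",
              x$temperature, kBT(x)))
  cat(sprintf("  cylinder R   = %.4g Angstrom\n", x$cylinder_radius))
  cat(sprintf("  c0           = %.4g mol/L\n", x$standard_conc))
  invisible(x)
}
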