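#' Physical constants used throughout the package
#'
#' All internal energies are in eV, distances in Angstrom, temperatures in
#' Kelvin. Time enters only through the reduced Planck constant when rates
#' (energy units) are converted to inverse seconds, and through the conductance
#' quantum when dimensionless contractions are converted to Siemens.
#'
#' @format A named list with elements:
#' \describe{
#'   \item{kB}{Boltzmann constant, eV/K (8.617333262e-5).}
#'   \item{hbar_eVs}{Reduced Planck constant, eV s.}
#'   \item{e2_over_h}{Conductance quantum per spin, e^2/h, in Siemens.}
#'   \item{e2_over_hbar}{e^2/hbar = 2 pi e^2/h, in Siemens.}
#'   \item{bohr_A}{Bohr radius in Angstrom.}
#' }
#' @export
mc_constants <- list(
  kB          = 8.617333262e-5,
  hbar_eVs    = 6.582119569e-16,
  e2_over_h   = 3.874045865e-5,
  e2_over_hbar = 2 * pi * 3.874045865e-5,
  bohr_A      = 0.529177210903
)

#' Thermal energy kT in eV
#'
#' @param T temperature in Kelvin.
#' @return kT in eV.
#' @export
kT_eV <- function(T) mc_constants$kB * T
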