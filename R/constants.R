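#' Physical constants and unit conventions
#'
#' All internal quantities are carried in a single unit system: lengths in
#' Angstrom, times in femtoseconds, masses in unified atomic mass units (amu)
#' and temperatures in Kelvin. Frequencies are reported as wavenumbers in
#' cm^-1 on output. Energies in these units are amu A^2 fs^-2
#' (1 amu A^2 fs^-2 = 1.66053906660e-17 J).
#'
#' `vib_constants` is a named list with elements:
#' \describe{
#'   \item{kB}{Boltzmann constant, amu A^2 fs^-2 K^-1 (CODATA exact value
#'     converted).}
#'   \item{c_cm_fs}{speed of light in cm/fs (CODATA exact).}
#'   \item{amu_kg}{1 amu in kg.}
#' }
#' @export
vib_constants <- list(
  # kB = 1.380649e-23 J/K / (1.66053906660e-27 kg * 1e-20 m^2 / 1e-30 s^2)
  kB      = 1.380649e-23 / 1.66053906660e-17,
  c_cm_fs = 2.99792458e-5,
  amu_kg  = 1.66053906660e-27
)

#' Convert an angular frequency (rad/fs) to a wavenumber (cm^-1)
#' @param omega angular frequency in rad/fs
#' @return wavenumber in cm^-1
#' @export
omega_to_wavenumber <- function(omega) omega / (2 * pi * vib_constants$c_cm_fs)

#' Convert a wavenumber (cm^-1) to an angular frequency (rad/fs)
#' @param nu wavenumber in cm^-1
#' @return angular frequency in rad/fs
#' @export
wavenumber_to_omega <- function(nu) nu * 2 * pi * vib_constants$c_cm_fs
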