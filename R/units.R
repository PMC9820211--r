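## Physical constants and unit conversions used throughout the package.
## Internal conventions: length nm, time fs in trajectories (ps inside the
## integrator), energy kT, frequency THz, field strength V/nm, charge e.

#' Physical constants
#'
#' Named list of the physical constants the package relies on, in the unit
#' system stated for each entry.
#'
#' @format A list with elements:
#' \describe{
#'   \item{c_m_s}{speed of light, m/s}
#'   \item{e_C}{elementary charge, C}
#'   \item{kB_kJ_mol_K}{Boltzmann constant, kJ/mol/K}
#'   \item{eV_kJ_mol}{1 eV in kJ/mol (also e * 1 V/nm in kJ/mol/nm terms)}
#'   \item{coulomb_kJ_mol_nm}{k_e * e^2 in kJ/mol * nm (vacuum)}
#'   \item{THz_cm1}{1 THz in wavenumbers, cm^-1}
#' }
#' @export
CONST <- list(
  c_m_s            = 299792458,
  e_C              = 1.602176634e-19,
  kB_kJ_mol_K      = 0.00831446262,
  eV_kJ_mol        = 96.48533212,
  coulomb_kJ_mol_nm = 138.935458,
  THz_cm1          = 33.35640952
)

#' Thermal energy in kJ/mol
#'
#' @param temperature Temperature in kelvin.
#' @return kT in kJ/mol.
#' @keywords internal
kT_kJ_mol <- function(temperature) CONST$kB_kJ_mol_K * temperature

#' Convert a vacuum wavelength to frequency
#'
#' `f = c / lambda`.  A 5.6 micron midinfrared line corresponds to
#' 53.53 THz.
#'
#' @param lambda_um Wavelength in micrometres (> 0).
#' @return Frequency in THz.
#' @examples
#' wavelength_to_frequency(5.6)   # 53.53 THz
#' @export
wavelength_to_frequency <- function(lambda_um) {
  if (!is.numeric(lambda_um) || any(!is.finite(lambda_um)) || any(lambda_um <= 0))
    stop("wavelength must be a positive finite number (micrometres)")
  CONST$c_m_s / (lambda_um * 1e-6) / 1e12
}

#' Convert a frequency in THz to wavenumbers
#'
#' @param f_thz Frequency in THz.
#' @return Wavenumber in cm^-1 (1 THz = 33.356 cm^-1).
#' @export
thz_to_wavenumber <- function(f_thz) f_thz * CONST$THz_cm1

#' Magnetic-to-electric force ratio for a moving ion
#'
#' For an ion moving at speed v in an electromagnetic wave, the ratio of the
#' magnetic (Lorentz) force to the electric force is v/c, which justifies
#' neglecting the magnetic component at thermal ion speeds.
#'
#' @param speed Ion speed in m/s, `0 <= speed <= c`.
#' @return Dimensionless ratio v/c.
#' @examples
#' force_ratio(300)   # ~1e-6: magnetic force negligible
#' @export
force_ratio <- function(speed) {
  if (!is.numeric(speed) || any(!is.finite(speed)) || any(speed < 0))
    stop("speed must be a finite non-negative number (m/s)")
  if (any(speed > CONST$c_m_s))
    stop("speed exceeds the speed of light")
  speed / CONST$c_m_s
}

## package-level logging: message() gated on an option so pipelines can
## silence narration without suppressMessages()
tz_log <- function(..., verbose = getOption("thzchannel.verbose", TRUE)) {
  if (isTRUE(verbose)) message(...)
  invisible(NULL)
}
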