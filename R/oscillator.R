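## Damped driven harmonic oscillator standing in for the carbonyl (-C=O)
## stretch of the filter backbone.  Driven at the field frequency it
## responds with a Lorentzian resonance; its mean excitation energy is what
## couples back onto the S1 barrier (see modulated_barrier()).

#' Carbonyl stretch oscillator
#'
#' A classical damped harmonic oscillator with natural frequency `f0`
#' (default 51.87 THz, the carbonyl fingerprint band), damping `gamma`
#' (Lorentzian FWHM `gamma/2/pi` THz; the observed band is under 2 THz
#' wide), effective charge `q_eff` and reduced mass `mass` (C=O reduced
#' mass, 6.86 amu).
#'
#' @param f0 Natural frequency in THz (> 0).
#' @param gamma Damping rate in 1/ps; the underdamped regime requires
#'   `gamma/2 < 2*pi*f0`.
#' @param q_eff Effective charge in e.
#' @param mass Reduced mass in amu.
#' @param x0,v0 Initial displacement (nm) and velocity (nm/ps).
#' @return An object of class `carbonyl_oscillator`.
#' @export
carbonyl_oscillator <- function(f0 = 51.87, gamma = 6, q_eff = 1,
                                mass = 6.86, x0 = 0, v0 = 0) {
  if (f0 <= 0) stop("f0 must be positive (THz)")
  if (gamma <= 0) stop("gamma must be positive (1/ps)")
  if (mass <= 0) stop("mass must be positive (amu)")
  if (gamma / 2 >= 2 * pi * f0)
    stop("overdamped oscillator: require gamma/2 < 2*pi*f0")
  structure(list(f0 = f0, gamma = gamma, q_eff = q_eff, mass = mass,
                 x0 = x0, v0 = v0),
            class = "carbonyl_oscillator")
}

#' @export
print.carbonyl_oscillator <- function(x, ...) {
  cat(sprintf("<carbonyl_oscillator> f0 = %g THz, gamma = %g /ps (FWHM %.3g THz), q_eff = %g e, m = %g amu\n",
              x$f0, x$gamma, x$gamma / (2 * pi), x$q_eff, x$mass))
  invisible(x)
}

#' Integrate the driven oscillator and return its dipole trace
#'
#' Solves `m x'' = -m w0^2 x - m gamma x' + q_eff E0 cos(2 pi f t + phi)`
#' deterministically with `deSolve::ode` (lsoda) on a uniform output grid
#' and returns the dipole `mu(t) = q_eff x(t)` together with displacement
#' and velocity columns for energy bookkeeping.
#'
#' @param osc A [carbonyl_oscillator()].
#' @param field A [field_spec()] (drive amplitude `E0` V/nm, frequency
#'   `f` THz).
#' @param dt_fs Output sampling step in fs; must resolve the natural
#'   period (`dt <= 1/(20 f0)`).
#' @param n_steps Number of integration steps; the trace has
#'   `n_steps + 1` samples.
#' @return A [dipole_trace()] with extra columns `x` (nm) and `v` (nm/ps)
#'   and attribute `osc`.
#' @export
drive_oscillator <- function(osc, field, dt_fs = 0.5, n_steps = 20000L) {
  stopifnot(inherits(osc, "carbonyl_oscillator"), inherits(field, "field_spec"))
  if (dt_fs <= 0 || n_steps < 64L)
    stop("need dt_fs > 0 and n_steps >= 64")
  if (dt_fs > 1000 / (20 * osc$f0))
    stop(sprintf("dt = %g fs cannot resolve f0 = %g THz; need dt <= %.3g fs",
                 dt_fs, osc$f0, 1000 / (20 * osc$f0)))
  w0 <- 2 * pi * osc$f0        # rad/ps
  wd <- 2 * pi * field$f
  famp <- osc$q_eff * field$E0 * CONST$eV_kJ_mol / osc$mass  # nm/ps^2
  times_ps <- seq(0, n_steps) * dt_fs * 1e-3
  deriv <- function(t, y, p) {
    list(c(y[2L],
           -w0^2 * y[1L] - osc$gamma * y[2L] + famp * cos(wd * t + field$phi)))
  }
  sol <- deSolve::ode(c(x = osc$x0, v = osc$v0), times_ps, deriv, NULL,
                      method = "lsoda", rtol = 1e-10, atol = 1e-12)
  tr <- dipole_trace(times_ps * 1e3, osc$q_eff * sol[, "x"])
  tr$x <- sol[, "x"]; tr$v <- sol[, "v"]
  attr(tr, "osc") <- osc
  attr(tr, "field") <- field
  tr
}

#' Closed-form steady-state amplitude of the driven oscillator
#'
#' `A(f) = (q_eff E0 / m) / sqrt((w0^2 - w^2)^2 + gamma^2 w^2)` with
#' `w = 2 pi f`; the Lorentzian response the integrator must reproduce.
#'
#' @param osc A [carbonyl_oscillator()].
#' @param field A [field_spec()].
#' @return Steady-state displacement amplitude in nm.
#' @export
lorentzian_amplitude <- function(osc, field) {
  w0 <- 2 * pi * osc$f0
  w <- 2 * pi * field$f
  famp <- osc$q_eff * field$E0 * CONST$eV_kJ_mol / osc$mass
  famp / sqrt((w0^2 - w^2)^2 + osc$gamma^2 * w^2)
}

#' Mean steady-state oscillator energy
#'
#' Total (kinetic + potential) energy averaged over the last
#' `1 - discard_fraction` of the trace, in kT at the given temperature.
#'
#' @param trace A trace from [drive_oscillator()].
#' @param temperature Temperature in kelvin used for the kT scale.
#' @param discard_fraction Initial fraction of the trace dropped as
#'   transient (default 0.5).
#' @return Mean energy in kT.
#' @export
oscillator_energy <- function(trace, temperature = 300, discard_fraction = 0.5) {
  osc <- attr(trace, "osc")
  if (is.null(osc)) stop("trace does not carry oscillator metadata")
  n <- length(trace$mu)
  keep <- seq.int(floor(n * discard_fraction) + 1L, n)
  w0 <- 2 * pi * osc$f0
  e_kj <- mean(0.5 * osc$mass * trace$v[keep]^2 +
                 0.5 * osc$mass * w0^2 * trace$x[keep]^2)  # amu nm^2/ps^2 = kJ/mol
  e_kj / kT_kJ_mol(temperature)
}

#' Steady-state oscillator energy from the closed form
#'
#' `<E> = m A^2 (w^2 + w0^2) / 4` in kT: the value [oscillator_energy()]
#' estimates from an integrated trace.
#'
#' @inheritParams lorentzian_amplitude
#' @param temperature Temperature in kelvin.
#' @return Mean steady-state energy in kT.
#' @export
steady_state_energy <- function(osc, field, temperature = 300) {
  A <- lorentzian_amplitude(osc, field)
  w0 <- 2 * pi * osc$f0
  w <- 2 * pi * field$f
  osc$mass * A^2 * (w^2 + w0^2) / 4 / kT_kJ_mol(temperature)
}
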