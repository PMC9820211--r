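## Reduced-scale channel simulator: overdamped Langevin dynamics of ions and
## waters on the pore axis under the multi-well binding landscape, a
## membrane-voltage tilt, the oscillating field, screened ion-ion Coulomb
## repulsion and single-file exclusion, with recycling boundaries emulating
## the double-membrane periodic setup.

PARTICLE_MASS <- c(K = 39.0983, W = 18.0153, O = 15.999, CL = 35.453)
PARTICLE_CHARGE <- c(K = 1, W = 0, O = 0, CL = -1)

#' Run the Langevin channel simulator
#'
#' Propagates `n_ions` potassium ions and `n_waters` waters with
#' Euler-Maruyama overdamped dynamics.  Forces on an ion: the landscape
#' gradient, the membrane-voltage tilt (a constant field across the whole
#' box), the oscillating field `q E0 cos(2 pi f t + phi)`, and screened
#' Coulomb repulsion from other ions.  Waters feel the landscape at
#' `water_scale` strength and the single-file exclusion but carry no
#' monopole charge, so they ignore both fields.  The thermal noise obeys
#' fluctuation-dissipation at `config$temperature`; a particle leaving one
#' end of the box re-enters at the other (recycling).
#'
#' When the field drives a landscape with `kappa > 0`, the carbonyl
#' oscillator is integrated first; its steady-state energy lowers the S1
#' entry barrier through [modulated_barrier()] before the particle dynamics
#' run (the oscillator reaches steady state within picoseconds, so the
#' coupling is treated as quasi-static).
#'
#' @param config A [run_config()].
#' @param landscape A [landscape_potential()]; default [default_landscape()].
#' @param n_ions,n_waters Particle counts (`>= 0`).
#' @param osc Carbonyl oscillator used when `landscape$kappa > 0` and the
#'   field is on; default [carbonyl_oscillator()].
#' @return A `sim_result`: list with `trajectory` ([trajectory()],
#'   `n_steps/sample_stride + 1` frames), `dipole_trace` (oscillator
#'   response, `NULL` when no field is applied), `field`, `seed`,
#'   `landscape` (the landscape actually used, after any modulation) and
#'   `config`.  Same config and seed give bit-identical output.
#' @examples
#' cfg <- run_config(n_steps = 2000L, seed = 1L)
#' res <- simulate_channel(cfg, n_ions = 2, n_waters = 2)
#' res$trajectory
#' @export
simulate_channel <- function(config, landscape = default_landscape(),
                             n_ions = 3L, n_waters = 3L,
                             osc = carbonyl_oscillator()) {
  stopifnot(inherits(config, "run_config"), inherits(landscape, "landscape"))
  n_ions <- as.integer(n_ions); n_waters <- as.integer(n_waters)
  if (n_ions < 0L || n_waters < 0L) stop("particle counts must be >= 0")
  if (n_ions + n_waters == 0L) stop("nothing to simulate: no particles")
  sm <- config$sitemap
  kT <- kT_kJ_mol(config$temperature)

  ## resonance coupling: oscillator energy lowers the S1 entry barrier
  dip <- NULL
  ls_used <- landscape
  if (config$field$E0 > 0) {
    dip <- drive_oscillator(osc, config$field, dt_fs = 0.5, n_steps = 10000L)
    if (landscape$kappa > 0) {
      e_osc <- oscillator_energy(dip, temperature = config$temperature)
      ls_used <- modulated_barrier(landscape, e_osc)
      tz_log(sprintf("simulate_channel: oscillator energy %.3f kT lowers the S1 top by %.3f kT",
                     e_osc, landscape$kappa * e_osc))
    }
  }

  species <- c(rep("K", n_ions), rep("W", n_waters))
  id <- paste0(species, c(seq_len(n_ions), seq_len(n_waters)))
  D <- kT / (PARTICLE_MASS[species] * config$friction)   # nm^2/ps
  charge <- PARTICLE_CHARGE[species]
  vscale <- ifelse(species == "W", config$water_scale, 1)

  z0 <- initial_positions(ls_used, sm, n_ions, n_waters, config$d_min)
  ex <- ls_used$extrema
  pore_lo <- ex$z[1L]; pore_hi <- ex$z[length(ex$z)]
  z_min <- min(sm$z_lo); z_max <- max(sm$z_hi)
  max_step <- min(sm$z_hi - sm$z_lo) / 2

  field_force <- config$field$E0 * CONST$eV_kJ_mol / kT          # kT/nm per e
  ## constant-field method: the voltage drops uniformly across the box
  tilt_force <- config$membrane_voltage * 1e-3 * CONST$eV_kJ_mol /
    (z_max - z_min) / kT                                         # kT/nm per e
  omega <- 2 * pi * config$field$f                               # rad/ps

  ## landscape energies are absolute: kT at the 300 K reference.  At other
  ## temperatures the force (in local thermal units) rescales accordingly,
  ## so cooling sharpens the wells instead of erasing them.
  V_scaled <- ex$V * kT_kJ_mol(300) / kT
  set.seed(config$seed)
  res <- sim_core(z0, D, charge, vscale, ex$z, V_scaled,
                  dt = config$dt_fs * 1e-3,
                  n_steps = config$n_steps, stride = config$sample_stride,
                  field_force = field_force, omega = omega,
                  phi = config$field$phi, tilt_force = tilt_force,
                  pore_lo = pore_lo, pore_hi = pore_hi,
                  z_min = z_min, z_max = z_max,
                  coul_pref = CONST$coulomb_kJ_mol_nm / config$epsilon_r / kT,
                  lambda_d = config$debye_nm, d_min = config$d_min,
                  max_step = max_step)

  times_fs <- seq(0L, config$n_steps %/% config$sample_stride) *
    config$sample_stride * config$dt_fs
  traj <- trajectory(times_fs, res$z, species, id = id,
                     box_z = z_max - z_min,
                     metadata = list(temperature = config$temperature,
                                     seed = config$seed,
                                     E0 = config$field$E0,
                                     f_thz = config$field$f,
                                     phi = config$field$phi,
                                     membrane_voltage = config$membrane_voltage,
                                     charge_imbalance_dq = config$charge_imbalance_dq,
                                     friction = config$friction))
  tz_log(sprintf("simulate_channel: %d steps (%.4g ns), %d ions + %d waters, seed %d",
                 config$n_steps, config$n_steps * config$dt_fs * 1e-6,
                 n_ions, n_waters, config$seed))
  structure(list(trajectory = traj, dipole_trace = dip, field = config$field,
                 seed = config$seed, landscape = ls_used, config = config),
            class = "sim_result")
}

#' @export
print.sim_result <- function(x, ...) {
  cat("<sim_result>\n")
  print(x$trajectory)
  if (!is.null(x$dipole_trace)) print(x$dipole_trace)
  invisible(x)
}

## Deterministic starting configuration: ions on alternating wells from the
## extracellular end (mimicking the alternating filter loading), waters in
## the remaining wells, leftovers spaced through the intracellular reservoir.
initial_positions <- function(ls, sm, n_ions, n_waters, d_min) {
  nw <- length(ls$centers)
  ion_wells <- rev(seq(nw, 1L, by = -2L))
  wat_wells <- rev(seq(nw - 1L, 1L, by = -2L))
  res_lo <- min(sm$z_lo) + 0.05
  res_hi <- ls$extrema$z[1L] - 0.05
  reservoir <- function(k) {
    spacing <- max(d_min, 0.05)
    rng <- max(res_hi - res_lo, 0.1)
    res_lo + ((k - 1L) * spacing) %% rng
  }
  z_ions <- z_wats <- numeric(0)
  if (n_ions > 0L) {
    take <- utils::head(ion_wells, n_ions)
    extra <- n_ions - length(take)
    z_ions <- c(ls$centers[take], if (extra > 0) reservoir(seq_len(extra)))
  }
  if (n_waters > 0L) {
    take <- utils::head(wat_wells, n_waters)
    extra <- n_waters - length(take)
    z_wats <- c(ls$centers[take],
                if (extra > 0) reservoir(extra + seq_len(extra)) + 0.02)
  }
  c(z_ions, z_wats)
}
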