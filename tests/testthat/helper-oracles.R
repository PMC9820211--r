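# Independent oracles used across the suite.  These deliberately avoid the
# code paths they validate: the MFPT oracle integrates the 1-D
# Smoluchowski double integral on a grid, and the script bookkeeping
# builders construct occupancy/mechanism ground truth by explicit
# enumeration.

options(thzchannel.verbose = FALSE)

# mean first passage time (ps) from z_min (reflecting) to z_max (absorbing)
# for a single ion: T = (1/D) int e^{U(y)} int_{zmin}^{y} e^{-U(x)} dx dy,
# U in kT including the constant-field tilt over the whole box
oracle_mfpt_ps <- function(ls, volt_mV, z_min, z_max, temperature = 300,
                           friction = 5, mass = 39.0983, n_grid = 48001) {
  kT <- 0.00831446262 * temperature
  D <- kT / (mass * friction)
  f_tilt <- volt_mV * 1e-3 * 96.48533212 / (z_max - z_min) / kT
  g <- seq(z_min, z_max, length.out = n_grid)
  dz <- g[2] - g[1]
  U <- landscape_energy(ls, g) - f_tilt * (g - z_min)
  sum(exp(U) * cumsum(exp(-U)) * dz) * dz / D
}

# Boltzmann site weights for a single particle on a landscape: integral of
# exp(-V) over each site interval (trapezoid on a fine grid)
oracle_site_weights <- function(ls, sitemap, n_grid = 20001) {
  g <- seq(min(sitemap$z_lo), max(sitemap$z_hi), length.out = n_grid)
  w <- exp(-landscape_energy(ls, g))
  reg <- site_of(g, sitemap)
  tapply(w, reg, sum)[sitemap$name] / sum(w)
}

# --- scripted knock-on event blocks --------------------------------------
# Each block drives ion K1 through a complete intracellular -> extracellular
# transit with partner ion K2 (and water W1) arranged so that the transit is
# water-separated (soft) or in direct contact (direct), then resets all
# particles to the intracellular reservoir.  Particles: K1, K2, W1.

soft_block <- function() {
  matrix(c(
    "intracellular", "intracellular", "intracellular",
    "Scav",          "intracellular", "intracellular",
    "S4",            "intracellular", "intracellular",
    "S3",            "intracellular", "Scav",
    "S2",            "Scav",          "S4",
    "S1",            "S4",            "S3",
    "S0",            "S3",            "S2",
    "extracellular", "S3",            "S2",
    "intracellular", "S4",            "S3",
    "intracellular", "Scav",          "S4",
    "intracellular", "intracellular", "Scav",
    "intracellular", "intracellular", "intracellular"
  ), ncol = 3, byrow = TRUE)
}

direct_block <- function() {
  matrix(c(
    "intracellular", "intracellular", "intracellular",
    "Scav",          "intracellular", "intracellular",
    "S4",            "Scav",          "intracellular",
    "S3",            "S4",            "intracellular",
    "S2",            "S3",            "intracellular",
    "S1",            "S2",            "intracellular",
    "S0",            "S1",            "intracellular",
    "extracellular", "S1",            "intracellular",
    "intracellular", "S2",            "intracellular",
    "intracellular", "S3",            "intracellular",
    "intracellular", "S4",            "intracellular",
    "intracellular", "Scav",          "intracellular",
    "intracellular", "intracellular", "intracellular"
  ), ncol = 3, byrow = TRUE)
}

# script with one permeation event per entry of `mechs`
knockon_script <- function(mechs) {
  blocks <- lapply(mechs, function(m)
    if (m == "soft") soft_block() else direct_block())
  list(species = c("K", "K", "W"),
       regions = do.call(rbind, blocks))
}

# random mixture of soft/direct/failed-attempt blocks under a fixed seed;
# returns the script plus its ground truth
random_knockon_script <- function(seed, n_blocks = 12) {
  set.seed(seed)
  mechs <- sample(c("soft", "direct"), n_blocks, replace = TRUE)
  # failed attempt: K1 enters the filter and retreats; no event
  failed <- matrix(c(
    "intracellular", "intracellular", "intracellular",
    "Scav",          "intracellular", "intracellular",
    "S4",            "intracellular", "intracellular",
    "S3",            "intracellular", "intracellular",
    "S4",            "intracellular", "intracellular",
    "Scav",          "intracellular", "intracellular",
    "intracellular", "intracellular", "intracellular"
  ), ncol = 3, byrow = TRUE)
  rows <- list(); truth <- character(0)
  for (m in mechs) {
    if (stats::runif(1) < 0.3) rows[[length(rows) + 1L]] <- failed
    rows[[length(rows) + 1L]] <-
      if (m == "soft") soft_block() else direct_block()
    truth <- c(truth, m)
  }
  list(script = list(species = c("K", "K", "W"),
                     regions = do.call(rbind, rows)),
       mechanisms = truth)
}

# quick single-ion equilibrium run shared by PMF / occupancy tests
equilibrium_run <- function(landscape, seed, n_steps = 2000000L, dt_fs = 5,
                            stride = 40L, sitemap = default_site_map()) {
  cfg <- run_config(n_steps = n_steps, dt_fs = dt_fs, seed = seed,
                    membrane_voltage = 0, sample_stride = stride,
                    sitemap = sitemap, discard_time_ns = 0.2)
  simulate_channel(cfg, landscape, n_ions = 1L, n_waters = 0L)
}
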