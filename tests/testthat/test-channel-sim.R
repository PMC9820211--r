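# Langevin channel simulator: fixed points, determinism, Boltzmann
# statistics, single-file order, flux conservation, Arrhenius behaviour.

test_that("at vanishing temperature an ion parks at its well minimum", {
  cfg <- run_config(n_steps = 5000L, dt_fs = 10, temperature = 1e-3,
                    membrane_voltage = 0, seed = 1L, sample_stride = 10L,
                    discard_time_ns = 0)
  res <- simulate_channel(cfg, default_landscape(), n_ions = 1, n_waters = 0)
  z <- res$trajectory$z[, 1]
  expect_lt(max(abs(z - z[1])), 1e-3)
  expect_lt(abs(landscape_force(res$landscape, z[1])), 1e-6)
})

test_that("identical config and seed reproduce bit-identical output", {
  cfg <- run_config(n_steps = 20000L, seed = 77L, membrane_voltage = 100)
  a <- simulate_channel(cfg, n_ions = 3, n_waters = 3)
  b <- simulate_channel(cfg, n_ions = 3, n_waters = 3)
  expect_identical(a$trajectory$z, b$trajectory$z)
  cfg2 <- run_config(n_steps = 20000L, seed = 78L, membrane_voltage = 100)
  c2 <- simulate_channel(cfg2, n_ions = 3, n_waters = 3)
  expect_false(identical(a$trajectory$z, c2$trajectory$z))
})

test_that("the trajectory has n_steps/stride + 1 frames", {
  cfg <- run_config(n_steps = 1000L, sample_stride = 40L, seed = 2L,
                    discard_time_ns = 0)
  res <- simulate_channel(cfg, n_ions = 1, n_waters = 1)
  expect_identical(n_frames(res$trajectory), 1000L %/% 40L + 1L)
})

test_that("equilibrium site occupancy is Boltzmann-distributed", {
  sm <- default_site_map()
  ls <- default_landscape(depth = 2, barrier = 1)
  res <- equilibrium_run(ls, seed = 5L)
  z <- res$trajectory$z[res$trajectory$times_fs >= 0.2e6, 1]
  reg <- site_of(z, sm)
  want <- oracle_site_weights(ls, sm)
  # Monte-Carlo SE from 10 consecutive blocks
  blocks <- split(reg, cut(seq_along(reg), 10))
  for (site in sm$name) {
    frac <- mean(reg == site)
    per_block <- vapply(blocks, function(b) mean(b == site), 0)
    se <- stats::sd(per_block) / sqrt(length(per_block))
    expect_lt(abs(frac - want[[site]]), 3 * se + 0.01)
  }
})

test_that("net flux vanishes without voltage or field", {
  sm <- default_site_map()
  net <- vapply(1:3, function(s) {
    res <- equilibrium_run(default_landscape(depth = 2, barrier = 1),
                           seed = 100L + s, n_steps = 1000000L)
    ev <- detect_permeations(res$trajectory, sm)
    sum(ev$direction == "outward") - sum(ev$direction == "inward")
  }, 0)
  total <- sum(net)
  n_events <- max(sum(abs(net)), 1)
  expect_lt(abs(total), 3 * sqrt(n_events) + 1)
})

test_that("single-file order inside the pore is never violated", {
  cfg <- run_config(n_steps = 100000L, seed = 9L, membrane_voltage = 150)
  res <- simulate_channel(cfg, n_ions = 3, n_waters = 3)
  z <- res$trajectory$z
  sm <- cfg$sitemap
  pore_lo <- sm$z_hi[1]; pore_hi <- sm$z_lo[nrow(sm)]
  box <- res$trajectory$box_z
  swaps <- 0L
  for (f in 2:nrow(z)) {
    prev <- z[f - 1, ]; cur <- z[f, ]
    in_pore <- prev > pore_lo & prev < pore_hi & cur > pore_lo & cur < pore_hi
    wrapped <- abs(cur - prev) > box / 2
    idx <- which(in_pore & !wrapped)
    if (length(idx) > 1) {
      o <- order(prev[idx])
      if (is.unsorted(cur[idx][o])) swaps <- swaps + 1L
    }
  }
  expect_identical(swaps, 0L)
})

test_that("flux is conserved across the two counting planes", {
  sm <- arrhenius_site_map()
  cfg <- run_config(n_steps = 50000000L, dt_fs = 2, seed = 301L,
                    membrane_voltage = 150, sample_stride = 500L,
                    sitemap = sm, discard_time_ns = 2)
  res <- simulate_channel(cfg, arrhenius_landscape(), n_ions = 1, n_waters = 0)
  z <- res$trajectory$z[, 1]
  box <- res$trajectory$box_z
  net_crossings <- function(plane) {
    up <- z[-length(z)] < plane & z[-1] >= plane
    dn <- z[-length(z)] >= plane & z[-1] < plane
    wrap <- abs(diff(z)) > box / 2
    sum(up & !wrap) - sum(dn & !wrap)
  }
  n_entry <- net_crossings(sm$z_hi[sm$name == "intracellular"])
  n_exit <- net_crossings(sm$z_lo[sm$name == "extracellular"])
  expect_lte(abs(n_entry - n_exit), 2)
  # and the event counter sees the same net transport
  ev <- detect_permeations(res$trajectory, sm)
  n_net <- sum(ev$direction == "outward") - sum(ev$direction == "inward")
  expect_lte(abs(n_exit - n_net), 2)
  expect_gt(n_net, 5)
})

test_that("log-current is linear in a uniform barrier shift with slope -1", {
  sm <- arrhenius_site_map()
  shifts <- c(0, -0.6, -1.2)
  counts <- vapply(shifts, function(sh) {
    cfg <- run_config(n_steps = 75000000L, dt_fs = 2, seed = 42L,
                      membrane_voltage = 150, sample_stride = 500L,
                      sitemap = sm, discard_time_ns = 2)
    res <- simulate_channel(cfg, arrhenius_landscape(sh),
                            n_ions = 1, n_waters = 0)
    ev <- detect_permeations(res$trajectory, sm)
    sum(ev$direction == "outward") - sum(ev$direction == "inward")
  }, 0)
  expect_true(all(counts > 10))
  fit <- stats::lm(log(counts) ~ shifts)
  slope <- unname(stats::coef(fit)[2])
  se_slope <- sqrt(sum(1 / counts)) / sqrt(sum((shifts - mean(shifts))^2))
  expect_lt(abs(slope - (-1)), 3 * se_slope + 0.15)
})

test_that("raising the oscillator coupling can only speed conduction", {
  # Kramers monotonicity via the passage-time oracle on the modulated
  # landscapes (the coupling lowers the S1 entry barrier monotonically)
  ls <- default_landscape(depth = 2, barrier = 1.5, kappa = 1)
  e_osc <- steady_state_energy(carbonyl_oscillator(),
                               field_spec(0.4, 51.87), 300)
  kappas <- c(0, 0.3, 0.6, 1)
  times <- vapply(kappas, function(k) {
    lsk <- ls; lsk$kappa <- k
    m <- modulated_barrier(lsk, e_osc)
    oracle_mfpt_ps(m, volt_mV = 100, z_min = 0, z_max = 3)
  }, 0)
  expect_true(all(diff(times) < 0))
})

test_that("a too-large time step aborts with advice", {
  cfg <- run_config(n_steps = 1000L, dt_fs = 2000, seed = 3L,
                    discard_time_ns = 0)
  expect_error(simulate_channel(cfg, default_landscape(depth = 5, barrier = 3),
                                n_ions = 1, n_waters = 0), "smaller dt")
})

test_that("magnetic-to-electric force ratio is v/c", {
  expect_equal(force_ratio(CONST$c_m_s), 1)
  expect_equal(force_ratio(0), 0)
  expect_equal(force_ratio(300), 1.0007e-6, tolerance = 1e-4)
  expect_error(force_ratio(CONST$c_m_s + 1), "exceeds")
})

test_that("scripted trajectories reject impossible scripts", {
  expect_error(build_scripted_trajectory(list(regions = NULL)), "empty")
  expect_error(build_scripted_trajectory(
    list(species = "K",
         regions = matrix(c("intracellular", "S3"), ncol = 1))),
    "jumps over")
  expect_error(build_scripted_trajectory(
    list(species = c("K", "K"),
         regions = matrix(c("S3", "S2",
                            "S2", "S3"), ncol = 2, byrow = TRUE))),
    "pass through")
  expect_error(build_scripted_trajectory(
    list(species = c("K", "W"),
         regions = matrix(c("S2", "S2"), ncol = 2))),
    "share site")
  expect_error(build_scripted_trajectory(
    list(species = "K", regions = matrix("S9", 1, 1))), "absent")
})
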