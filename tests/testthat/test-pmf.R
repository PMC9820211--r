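# Boltzmann-inversion PMF and per-site barrier extraction.

test_that("uniform density inverts to a flat zero profile", {
  set.seed(3)
  z <- matrix(runif(200000, 0, 3), ncol = 1)
  tr <- trajectory(seq_len(nrow(z)) * 1000, z, "K", box_z = 3)
  prof <- compute_pmf(tr, z_range = c(0, 3), bin_width = 0.1)
  expect_lt(max(prof$W_kT, na.rm = TRUE), 0.15)
  expect_equal(min(prof$W_kT, na.rm = TRUE), 0)
})

test_that("two bins with density ratio e differ by exactly 1 kT", {
  z <- matrix(c(rep(0.25, 2718), rep(0.75, 1000)), ncol = 1)
  tr <- trajectory(seq_len(nrow(z)) * 1000, z, "K", box_z = 1)
  prof <- compute_pmf(tr, z_range = c(0, 1), bin_width = 0.5)
  expect_equal(prof$W_kT[2] - prof$W_kT[1], log(2718 / 1000),
               tolerance = 1e-12)
  expect_equal(prof$W_kT[2], 1, tolerance = 1e-3)
})

test_that("Gaussian samples recover the quadratic well curvature", {
  # Boltzmann density of 0.5*k*z^2 with sd 0.1 nm => k = 100 kT/nm^2
  set.seed(11)
  z <- matrix(rnorm(1e6, mean = 1.5, sd = 0.1), ncol = 1)
  tr <- trajectory(seq_len(nrow(z)), z, "K", box_z = 3)
  prof <- compute_pmf(tr, z_range = c(1.2, 1.8), bin_width = 0.02)
  sel <- !is.na(prof$W_kT) & abs(prof$z_nm - 1.5) < 0.25 &
    prof$n_samples > 200
  fit <- stats::lm(W ~ I((z - 1.5)^2),
                   data = data.frame(z = prof$z_nm[sel], W = prof$W_kT[sel]))
  k_hat <- 2 * unname(stats::coef(fit)[2])
  expect_equal(k_hat, 100, tolerance = 0.05)
})

test_that("empty bins are flagged NA, never interpolated", {
  z <- matrix(c(rep(0.25, 500), rep(1.25, 500)), ncol = 1)
  tr <- trajectory(seq_len(1000) * 1000, z, "K", box_z = 2)
  prof <- compute_pmf(tr, z_range = c(0, 2), bin_width = 0.5)
  expect_true(is.na(prof$W_kT[2]))
  expect_identical(prof$n_samples[2], 0L)
  expect_error(compute_pmf(tr, z_range = c(1.6, 1.9)), "no samples")
})

test_that("equilibrium simulation recovers the input landscape within 0.3 kT RMS", {
  sm <- default_site_map()
  ls <- default_landscape(depth = 2, barrier = 1)
  res <- equilibrium_run(ls, seed = 23L, n_steps = 4000000L, stride = 20L)
  prof <- compute_pmf(res$trajectory, bin_width = 0.04,
                      discard_time_ns = 0.2, z_range = c(0.4, 2.8))
  expect_true(isTRUE(attr(prof, "equilibrium")))
  sel <- !is.na(prof$W_kT) & prof$n_samples >= 20
  truth <- landscape_energy(ls, prof$z_nm[sel])
  resid <- prof$W_kT[sel] - (truth - min(truth))
  resid <- resid - mean(resid)          # common reference constant
  rms <- sqrt(mean(resid^2))
  expect_lt(rms, 0.3)
})

test_that("barriers come from the max between well minima, both directions", {
  sm <- site_map(c("intracellular", "S4", "S3", "S2", "S1", "extracellular"),
                 c(0, 0.5, 1.0, 1.5, 2.0, 2.5),
                 c(0.5, 1.0, 1.5, 2.0, 2.5, 3.0))
  # symmetric double well, 3 kT deep, on S3/S2 with a top between
  zg <- seq(0.5, 2.5, by = 0.02) + 0.01
  W <- 3 - 3 * exp(-(zg - 1.25)^2 / 0.01) - 3 * exp(-(zg - 1.75)^2 / 0.01)
  prof <- structure(data.frame(z_nm = zg, W_kT = W - min(W),
                               n_samples = rep(100L, length(zg))),
                    class = c("pmf_profile", "data.frame"),
                    bin_width = 0.02, temperature = 300, equilibrium = TRUE)
  bars <- site_barriers(prof, sm)
  fw <- bars$barrier_kT[bars$from == "S3" & bars$to == "S2"]
  bw <- bars$barrier_kT[bars$from == "S2" & bars$to == "S3"]
  expect_equal(fw, bw, tolerance = 1e-9)
  expect_equal(fw, 3, tolerance = 0.01)
  # random piecewise profiles agree with a brute-force scan
  set.seed(8)
  for (i in 1:5) {
    Wr <- stats::runif(length(zg), 0, 4)
    profr <- prof; profr$W_kT <- Wr - min(Wr)
    bars <- site_barriers(profr, sm)
    wells <- sm[!(sm$name %in% c("intracellular", "extracellular")), ]
    mins <- vapply(seq_len(nrow(wells)), function(k) {
      sel <- which(zg >= wells$z_lo[k] & zg < wells$z_hi[k])
      sel[which.min(profr$W_kT[sel])]
    }, 0L)
    for (k in seq_len(nrow(wells) - 1L)) {
      top <- max(profr$W_kT[mins[k]:mins[k + 1]])
      expect_equal(bars$barrier_kT[bars$from == wells$name[k] &
                                     bars$to == wells$name[k + 1]],
                   top - profr$W_kT[mins[k]])
    }
  }
})

test_that("reference shifts leave barriers unchanged", {
  zg <- seq(0.5, 2.5, by = 0.02) + 0.01
  sm <- site_map(c("intracellular", "S4", "S3", "S2", "S1", "extracellular"),
                 c(0, 0.5, 1.0, 1.5, 2.0, 2.5),
                 c(0.5, 1.0, 1.5, 2.0, 2.5, 3.0))
  set.seed(9)
  W <- stats::runif(length(zg), 0, 4)
  mk <- function(W) structure(
    data.frame(z_nm = zg, W_kT = W, n_samples = rep(10L, length(zg))),
    class = c("pmf_profile", "data.frame"), bin_width = 0.02,
    temperature = 300, equilibrium = TRUE)
  b1 <- site_barriers(mk(W), sm)
  b2 <- site_barriers(mk(W + 2.5), sm)
  expect_equal(b1$barrier_kT, b2$barrier_kT)
})

test_that("driven-run profiles are labelled quasi-PMF", {
  cfg <- run_config(n_steps = 50000L, seed = 4L, membrane_voltage = 150,
                    field = field_spec(0.4, 51.87), discard_time_ns = 0)
  res <- simulate_channel(cfg, n_ions = 2, n_waters = 1)
  prof <- compute_pmf(res$trajectory, bin_width = 0.1)
  expect_false(attr(prof, "equilibrium"))
  p <- file.path(tempdir(), "pmf.tsv")
  write_pmf(prof, p)
  expect_true(any(grepl("quasi-PMF", readLines(p))))
})
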