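# Trajectory container, site map and file round trips.

random_trajectory <- function(seed, n_frames = 7, n_part = 4, with_xy = TRUE) {
  set.seed(seed)
  species <- sample(c("K", "W", "O", "CL"), n_part, replace = TRUE)
  trajectory(times_fs = (seq_len(n_frames) - 1) * 500,
             z = matrix(runif(n_frames * n_part, 0, 3), n_frames),
             species = species,
             x = if (with_xy) matrix(runif(n_frames * n_part, -1, 1), n_frames),
             y = if (with_xy) matrix(runif(n_frames * n_part, -1, 1), n_frames),
             box_z = 3, metadata = list(temperature = 300, seed = seed))
}

test_that("trajectory constructor enforces its invariants", {
  tr <- trajectory(c(0, 2), matrix(c(1, 1.1), 2, 1), "K", box_z = 3)
  expect_s3_class(tr, "trajectory")
  expect_equal(frame_dt(tr), 2)
  # non-uniform spacing beyond 1 ppm
  expect_error(trajectory(c(0, 2, 4.1), matrix(0.5, 3, 1), "K", box_z = 3),
               "non-uniform")
  # a 1 ppm wobble is tolerated
  expect_silent(trajectory(c(0, 2, 4 + 2e-7), matrix(0.5, 3, 1), "K",
                           box_z = 3))
  expect_error(trajectory(c(0, 2), matrix(c(1, NA), 2, 1), "K", box_z = 3),
               "gap")
  expect_error(trajectory(0, matrix(1, 1, 1), "X", box_z = 3),
               "unknown species")
  expect_error(trajectory(c(0, 1), matrix(1, 2, 2), c("K", "K"),
                          id = c("a", "a"), box_z = 3), "unique")
})

test_that("columnar trajectory files read back what was written", {
  p <- file.path(tempdir(), "traj.tsv")
  # 2-frame 1-ion echo
  tr <- trajectory(c(0, 2), matrix(c(1, 1.25), 2, 1), "K", box_z = 3)
  write_trajectory(tr, p)
  rt <- read_trajectory(p)
  expect_equal(frame_dt(rt), 2)
  expect_equal(rt$z, tr$z, tolerance = 1e-6)
  # property: round trip of random trajectories to 6 decimals
  for (seed in 1:5) {
    tr <- random_trajectory(seed)
    write_trajectory(tr, p)
    rt <- read_trajectory(p)
    expect_equal(rt$z, tr$z, tolerance = 2e-6)
    expect_equal(rt$x, tr$x, tolerance = 2e-6)
    expect_equal(rt$species, tr$species)
    expect_equal(rt$box_z, tr$box_z)
  }
})

test_that("columnar reader reports malformed and gapped input precisely", {
  p <- file.path(tempdir(), "bad.tsv")
  writeLines(c("0\tK1\tK\t1.0", "2\tK1\tK"), p)
  expect_error(read_trajectory(p), "line 2")
  writeLines(c("0\tK1\tK\t1.0", "0\tW1\tW\t2.0", "2\tK1\tK\t1.1"), p)
  expect_error(read_trajectory(p), "gap")
  writeLines(c("0\tK1\tK\tabc"), p)
  expect_error(read_trajectory(p), "non-numeric")
})

test_that("PDB snapshot series round-trips with nm/Angstrom conversion", {
  p <- file.path(tempdir(), "traj.pdb")
  tr <- trajectory(0, matrix(1, 1, 1), "K",
                   x = matrix(0.2, 1, 1), y = matrix(-0.3, 1, 1), box_z = 3)
  write_trajectory(tr, p, format = "pdb")
  txt <- readLines(p)
  atom <- grep("^ATOM", txt, value = TRUE)
  expect_length(atom, 1)
  expect_equal(as.numeric(substr(atom, 47, 54)), 10.000)  # 1 nm -> 10 A
  for (seed in 1:3) {
    tr <- random_trajectory(seed, n_frames = 4, n_part = 3)
    write_trajectory(tr, p, format = "pdb")
    rt <- read_trajectory(p, format = "pdb")
    expect_equal(rt$z, tr$z, tolerance = 1e-3,
                 ignore_attr = TRUE)  # PDB stores 3 decimals in Angstrom
    expect_equal(rt$species, tr$species)
    expect_equal(rt$times_fs, tr$times_fs)
  }
})

test_that("writing an empty trajectory fails loudly", {
  tr <- trajectory(c(0, 1), matrix(numeric(0), 2, 0), character(0), box_z = 3)
  expect_error(write_trajectory(tr, tempfile()), "no particles")
})

test_that("site membership is total and unique", {
  sm <- default_site_map()
  expect_error(site_map(c("S4", "S3", "S2"), c(0, 1, 2), c(1, 2, 3)),
               "missing")
  zs <- seq(-0.5, 3.5, by = 0.01)
  regions <- site_of(zs, sm)
  expect_true(all(regions %in% sm$name))
  # interior points fall in exactly one declared interval
  inside <- zs >= 0 & zs < 3
  for (i in which(inside)) {
    hits <- sum(zs[i] >= sm$z_lo & zs[i] < sm$z_hi)
    expect_identical(hits, 1L)
  }
  # half-open boundaries: a site's z_lo belongs to it, not its neighbour
  expect_identical(site_of(sm$z_lo[3], sm), "S4")
})

test_that("config files apply logged defaults and reject bad keys", {
  p <- file.path(tempdir(), "cfg.yml")
  writeLines(c("field:", "  E0: 0.4", "  f: 51.87", "  phi: 0"), p)
  msgs <- capture_messages(withr::with_options(
    list(thzchannel.verbose = TRUE), cfg <- load_config(p)))
  expect_true(any(grepl("default seed", msgs)))
  expect_equal(cfg$field$E0, 0.4)
  expect_equal(cfg$field$f, 51.87)
  expect_equal(cfg$field$phi, 0)
  expect_identical(cfg$seed, run_config()$seed)  # documented default
  writeLines(c("nonsense_key: 1"), p)
  expect_error(load_config(p), "valid keys")
  writeLines(c("temperature: -5"), p)
  expect_error(load_config(p), "temperature")
})
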