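# IR spectrum estimator, peak detection, band overlap, unit conversions.

damped_cosine <- function(period_fs, decay_fs, len_fs, dt_fs = 0.5,
                          amp = 1) {
  t <- seq(0, len_fs, by = dt_fs)
  dipole_trace(t, amp * exp(-t / decay_fs) * cos(2 * pi * t / period_fs))
}

test_that("a pure cosine of period 20 fs peaks at exactly 50 THz", {
  t <- seq(0, 5000, by = 0.5)
  sp <- ir_spectrum(dipole_trace(t, cos(2 * pi * t / 20)))
  expect_equal(sp$peaks$f_thz[1], 50, tolerance = 1e-3)
})

test_that("the carbonyl fingerprint period lands on 51.87 THz", {
  tr <- damped_cosine(19.279, 2000, 5e4)
  sp <- ir_spectrum(tr, window = "hann", pad_factor = 4)
  expect_equal(round(sp$peaks$f_thz[1], 2), 51.87)
})

test_that("two damped bands resolve with amplitude-ordered heights", {
  t <- seq(0, 2e4, by = 0.5)
  mu <- 2 * exp(-t / 3000) * cos(2 * pi * t * 0.040) +
    1 * exp(-t / 3000) * cos(2 * pi * t * 0.060)
  sp <- ir_spectrum(dipole_trace(t, mu), min_height_fraction = 0.02)
  pk <- sp$peaks[order(sp$peaks$f_thz), ]
  main <- pk[pk$height > 0.05 * max(pk$height), ]
  expect_identical(nrow(main), 2L)
  expect_equal(main$f_thz, c(40, 60), tolerance = 2e-3)
  expect_gt(main$height[1], main$height[2])
})

test_that("peak frequency tracks 1/period across the midinfrared band", {
  for (period in seq(10, 40, by = 6)) {
    sp <- ir_spectrum(damped_cosine(period, 1500, 2e4))
    expect_equal(sp$peaks$f_thz[1], 1000 / period,
                 tolerance = 2 * sp$df_thz / (1000 / period))
  }
})

test_that("spectral power equals time-domain variance (Parseval)", {
  set.seed(5)
  for (window in c("none", "hann")) {
    tr <- dipole_trace(seq(0, 499.5, by = 0.5), rnorm(1000))
    sp <- ir_spectrum(tr, window = window, pad_factor = 3)
    expect_equal(sp$parseval$spectral, sp$parseval$time_domain,
                 tolerance = 1e-6)
  }
})

test_that("trace validation rejects what the estimator cannot handle", {
  expect_error(dipole_trace(1:10, rnorm(10)), "64 samples")
  expect_error(dipole_trace(seq_len(100), c(rnorm(99), NaN)), "NaN")
  expect_error(dipole_trace(c(1:50, 50.5, 52:100), rnorm(100)), "uniform")
})

test_that("Lorentzian peaks are located and sized from the grid", {
  f <- seq(0, 100, by = 0.02)
  center <- 51.87; hwhm <- 0.4
  lor <- 1 / (1 + ((f - center) / hwhm)^2)
  sp <- structure(list(f_thz = f, absorption = lor, power = lor,
                       window = "none", pad_factor = 1, df_thz = 0.02,
                       parseval = NULL, peaks = NULL), class = "spectrum")
  pk <- find_peaks(sp, min_height_fraction = 0.1)
  expect_equal(pk$f_thz[1], center, tolerance = center * 0.005)
  expect_equal(pk$fwhm_thz[1], 2 * hwhm, tolerance = 2 * hwhm * 0.02)
  flat <- sp; flat$absorption <- rep(1, length(f))
  expect_identical(nrow(find_peaks(flat)), 0L)
})

test_that("band overlap matches the closed-form Gaussian inner product", {
  f <- seq(30, 70, by = 0.01)
  gauss_spec <- function(mu, sd) {
    a <- exp(-(f - mu)^2 / (2 * sd^2))
    structure(list(f_thz = f, absorption = a, power = a, window = "none",
                   pad_factor = 1, df_thz = 0.01, parseval = NULL,
                   peaks = NULL), class = "spectrum")
  }
  a <- gauss_spec(50, 2); b <- gauss_spec(53, 2)
  got <- band_overlap(a, b, c(40, 63))
  expect_equal(got, exp(-(53 - 50)^2 / (4 * 2^2)), tolerance = 0.01)
  expect_equal(band_overlap(a, a, c(40, 60)), 1)
  expect_equal(band_overlap(gauss_spec(35, 0.5), gauss_spec(65, 0.5),
                            c(30, 70)), 0, tolerance = 1e-6)
  bad <- gauss_spec(50, 2); bad$f_thz <- bad$f_thz + 0.005
  expect_error(band_overlap(a, bad, c(40, 60)), "different frequency grids")
})

test_that("wavelength, frequency and wavenumber conversions are exact", {
  expect_equal(round(wavelength_to_frequency(5.6), 2), 53.53)
  expect_equal(wavelength_to_frequency(299.792458), 1)
  expect_equal(round(wavelength_to_frequency(3.0), 2), 99.93)
  expect_error(wavelength_to_frequency(0), "positive")
  expect_equal(thz_to_wavenumber(1), 33.3564, tolerance = 1e-4)
})
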