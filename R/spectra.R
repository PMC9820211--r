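## IR absorption spectra from dipole time series.
##
## Estimator (fixed convention, identical across all calls): the absorption
## is the omega^2-weighted one-sided power spectrum of the mean-removed,
## Hann-windowed dipole, zero-padded by pad_factor.  By the Wiener-Khinchin
## theorem this equals the omega-weighted Fourier transform of the windowed
## dipole autocorrelation, the standard classical IR lineshape estimator.
## No quantum correction factor is applied.

#' Dipole time series
#'
#' @param t_fs Times in fs, uniformly spaced, at least 64 samples.
#' @param mu Scalar dipole values (arbitrary units); the z component when a
#'   3-vector has been reduced.
#' @return An object of class `dipole_trace` with elements `t_fs`, `mu`
#'   and the sampling step `dt_fs`.
#' @export
dipole_trace <- function(t_fs, mu) {
  t_fs <- as.numeric(t_fs); mu <- as.numeric(mu)
  if (length(t_fs) != length(mu)) stop("t_fs and mu must have equal length")
  if (length(t_fs) < 64L) stop("dipole trace needs at least 64 samples")
  if (anyNA(mu) || any(!is.finite(mu))) stop("NaN or non-finite value in dipole trace")
  dts <- diff(t_fs)
  if (any(dts <= 0)) stop("times must be strictly increasing")
  dt <- dts[1L]
  if (any(abs(dts - dt) > 1e-6 * dt)) stop("dipole trace must be uniformly sampled")
  structure(list(t_fs = t_fs, mu = mu, dt_fs = dt), class = "dipole_trace")
}

#' @export
print.dipole_trace <- function(x, ...) {
  cat(sprintf("<dipole_trace> %d samples, dt = %g fs (%.4g ps)\n",
              length(x$mu), x$dt_fs, length(x$mu) * x$dt_fs * 1e-3))
  invisible(x)
}

#' IR absorption spectrum of a dipole trace
#'
#' Computes `A(f) = omega^2 * |FFT(w(t) * (mu - mean(mu)))|^2` on the
#' one-sided frequency grid `f_k = k / (N_pad * dt)`, with `w` a Hann
#' window (or none) and `N_pad = pad_factor * N` zero-padding for finer
#' peak localisation.  Peaks are located with [find_peaks()] (quadratic
#' sub-bin interpolation).
#'
#' @param trace A [dipole_trace()].
#' @param window `"hann"` (default) or `"none"`.
#' @param pad_factor Integer `>= 1`; the signal is zero-padded to the next
#'   2-3-5-smooth length at least `pad_factor` times its own (default 4).
#' @param min_height_fraction Peak threshold passed to [find_peaks()].
#' @return An object of class `spectrum`: list with `f_thz`, `absorption`
#'   (`>= 0`), `power` (unweighted spectral density), `window`, `peaks`
#'   (data.frame `f_thz`, `height`, `fwhm_thz`), and `parseval` (list with
#'   the window-compensated time-domain variance and its spectral-sum
#'   estimate, equal up to roundoff).
#' @examples
#' t <- seq(0, 5e4, by = 0.5)                 # 50 ps at 0.5 fs
#' mu <- exp(-t / 2000) * cos(2 * pi * t / 19.279)
#' sp <- ir_spectrum(dipole_trace(t, mu))
#' sp$peaks$f_thz[1]                          # ~51.87 THz
#' @export
ir_spectrum <- function(trace, window = c("hann", "none"), pad_factor = 4L,
                        min_height_fraction = 0.05) {
  stopifnot(inherits(trace, "dipole_trace"))
  window <- match.arg(window)
  pad_factor <- as.integer(pad_factor)
  if (pad_factor < 1L) stop("pad_factor must be >= 1")
  x <- trace$mu - mean(trace$mu)
  n <- length(x)
  w <- if (window == "hann") {
    0.5 * (1 - cos(2 * pi * seq_len(n) / (n + 1)))  # periodic-free Hann
  } else rep(1, n)
  xw <- x * w
  ## pad to the next 2-3-5-smooth length >= pad_factor * n so the FFT stays
  ## O(n log n) for awkward trace lengths
  npad <- stats::nextn(n * pad_factor, c(2, 3, 5))
  ft <- stats::fft(c(xw, rep(0, npad - n)))
  dt_ps <- trace$dt_fs * 1e-3
  nhalf <- floor(npad / 2)
  f_thz <- (seq_len(nhalf + 1L) - 1L) / (npad * dt_ps)   # THz = 1/ps
  power <- Mod(ft[seq_len(nhalf + 1L)])^2 / n
  omega <- 2 * pi * f_thz
  absorption <- omega^2 * power
  ## Parseval check material: total two-sided power vs windowed variance
  parseval <- list(
    time_domain = mean(xw^2),
    spectral = sum(Mod(ft)^2) / npad / n
  )
  spec <- structure(list(f_thz = f_thz, absorption = absorption,
                         power = power, window = window,
                         pad_factor = pad_factor, df_thz = f_thz[2L],
                         parseval = parseval, peaks = NULL),
                    class = "spectrum")
  spec$peaks <- find_peaks(spec, min_height_fraction = min_height_fraction)
  spec
}

#' @export
print.spectrum <- function(x, ...) {
  cat(sprintf("<spectrum> %d bins, df = %.4g THz, window = %s\n",
              length(x$f_thz), x$df_thz, x$window))
  if (!is.null(x$peaks) && nrow(x$peaks))
    print(utils::head(x$peaks, 5))
  invisible(x)
}

#' Locate absorption peaks
#'
#' Local maxima above `min_height_fraction * max(absorption)`; each peak
#' frequency and height is refined by a quadratic fit through the three
#' bins around the maximum, and the FWHM is read off by linear
#' interpolation at half height.
#'
#' @param spec A `spectrum` from [ir_spectrum()].
#' @param min_height_fraction Minimum height relative to the global
#'   maximum (default 0.05).
#' @return data.frame with columns `f_thz`, `height`, `fwhm_thz`, sorted
#'   by decreasing height; zero rows when nothing exceeds the threshold.
#' @export
find_peaks <- function(spec, min_height_fraction = 0.05) {
  stopifnot(inherits(spec, "spectrum"))
  a <- spec$absorption; f <- spec$f_thz
  empty <- data.frame(f_thz = numeric(0), height = numeric(0),
                      fwhm_thz = numeric(0))
  if (max(a) <= 0) return(empty)
  thr <- min_height_fraction * max(a)
  pk <- pracma::findpeaks(a, minpeakheight = thr)
  if (is.null(pk)) return(empty)
  out <- lapply(seq_len(nrow(pk)), function(r) {
    i <- pk[r, 2L]
    if (i <= 1L || i >= length(a)) {
      fc <- f[i]; hc <- a[i]
    } else {
      y0 <- a[i - 1L]; y1 <- a[i]; y2 <- a[i + 1L]
      denom <- y0 - 2 * y1 + y2
      delta <- if (denom != 0) 0.5 * (y0 - y2) / denom else 0
      delta <- max(min(delta, 0.5), -0.5)
      fc <- f[i] + delta * spec$df_thz
      hc <- y1 - 0.25 * (y0 - y2) * delta
    }
    half <- hc / 2
    li <- i; while (li > 1L && a[li] > half) li <- li - 1L
    f_lo <- if (a[li] <= half && li < i)
      f[li] + (half - a[li]) / (a[li + 1L] - a[li]) * spec$df_thz else f[1L]
    ri <- i; while (ri < length(a) && a[ri] > half) ri <- ri + 1L
    f_hi <- if (a[ri] <= half && ri > i)
      f[ri - 1L] + (a[ri - 1L] - half) / (a[ri - 1L] - a[ri]) * spec$df_thz
      else f[length(f)]
    data.frame(f_thz = fc, height = hc, fwhm_thz = f_hi - f_lo)
  })
  out <- do.call(rbind, out)
  out[order(-out$height), , drop = FALSE]
}

#' Normalized band overlap of two spectra
#'
#' Cosine similarity (normalized inner product) of two absorption spectra
#' restricted to a frequency band; 1 for identical shapes, 0 for disjoint
#' bands.
#'
#' @param a,b `spectrum` objects on the same frequency grid.
#' @param band Length-2 numeric, band limits in THz.
#' @return Overlap fraction in `[0, 1]`.
#' @export
band_overlap <- function(a, b, band) {
  stopifnot(inherits(a, "spectrum"), inherits(b, "spectrum"))
  if (length(a$f_thz) != length(b$f_thz) ||
      any(abs(a$f_thz - b$f_thz) > 1e-9 * max(a$f_thz)))
    stop("spectra are on different frequency grids; resample before comparing")
  band <- sort(as.numeric(band))
  sel <- a$f_thz >= band[1L] & a$f_thz <= band[2L]
  if (!any(sel)) stop("band [", band[1L], ", ", band[2L],
                      "] THz has no support on the frequency grid")
  va <- a$absorption[sel]; vb <- b$absorption[sel]
  na <- sqrt(sum(va^2)); nb <- sqrt(sum(vb^2))
  if (na == 0 || nb == 0) return(0)
  max(0, min(1, sum(va * vb) / (na * nb)))
}

#' Write a spectrum as TSV
#' @param spec A `spectrum`.
#' @param path Output file (`f_THz  absorption`); peaks are appended as a
#'   companion `<path>.peaks` file (`f_THz  height  fwhm_THz`).
#' @return Invisibly, `path`.
#' @export
write_spectrum <- function(spec, path) {
  stopifnot(inherits(spec, "spectrum"))
  utils::write.table(data.frame(f_THz = spec$f_thz, absorption = spec$absorption),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(spec$peaks) && nrow(spec$peaks))
    utils::write.table(stats::setNames(spec$peaks,
                                       c("f_THz", "height", "fwhm_THz")),
                       paste0(path, ".peaks"), sep = "\t", quote = FALSE,
                       row.names = FALSE)
  invisible(path)
}
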