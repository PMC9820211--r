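## Multi-well binding landscape along the pore axis.
##
## The potential is a chain of cosine-smoothed segments between alternating
## extrema: reservoir anchors at V = 0, barrier tops at +barrier[i] kT and
## well minima at -depth[i] kT.  Between consecutive extrema (z1,V1),
## (z2,V2) the profile is V1 + (V2-V1)*(1-cos(pi*s))/2 with s the fractional
## position, which is C1 at every extremum (zero slope) and monotone within
## each segment, so well depths and barrier heights are exact by
## construction.

#' Multi-well binding landscape
#'
#' One well per binding site (typically Scav, S4..S0 or the five filter
#' wells S4..S0), with explicit barrier tops between adjacent wells and at
#' the two pore mouths.  Energies are in kT at the 300 K reference
#' (1 kT = 2.494 kJ/mol, an absolute scale, so cooling a simulation
#' sharpens the wells); the flat reservoirs define the zero of energy.
#'
#' @param centers Well centres in nm, strictly increasing; one per site.
#' @param depths Well depths in kT (positive numbers; the minima sit at
#'   `-depths`).  Scalar values are recycled.
#' @param barriers Barrier-top energies in kT relative to the reservoir
#'   level, length `length(centers) + 1`: entry top, the tops between
#'   adjacent wells, exit top.  Scalars are recycled.
#' @param names Optional well names (e.g. `c("Scav","S4","S3","S2","S1","S0")`).
#' @param kappa Coupling of the S1 entry barrier to the carbonyl-oscillator
#'   energy, in kT per kT of oscillator energy (default 0, i.e. a
#'   time-independent landscape).
#' @param s1_top Index (into `barriers`) of the barrier top that the
#'   resonant carbonyl excitation modulates: the top crossed going from S2
#'   into S1.  Defaults to the top below the well named `"S1"`, or the
#'   second-to-last top when no names are given.
#' @param edge_margin Distance (nm) from the outer tops to the reservoir
#'   anchors where the potential reaches 0 (default 0.15).
#' @param barrier_halfwidth Optional half-width (nm) of a flat plateau at
#'   each barrier crest.  By default a crest is a smooth cosine maximum
#'   whose curvature grows with its height; with a plateau the crest
#'   occupies `2 * barrier_halfwidth` at constant energy, so shifting the
#'   barrier top rescales the crest's Boltzmann weight exactly (pure
#'   Arrhenius behaviour, useful for barrier-controlled rate studies).
#' @param well_halfwidth Optional half-width (nm) of a flat floor at each
#'   well bottom (requires `barrier_halfwidth`).  Keeps the well Boltzmann
#'   weight independent of the adjacent barrier heights, removing the
#'   Kramers prefactor drift when barriers are shifted.
#' @return An object of class `landscape` with the validated fields plus
#'   the extrema table used for evaluation.
#' @seealso [landscape_energy()], [modulated_barrier()], [simulate_channel()]
#' @export
landscape_potential <- function(centers, depths, barriers, names = NULL,
                                kappa = 0, s1_top = NULL, edge_margin = 0.15,
                                barrier_halfwidth = NULL,
                                well_halfwidth = NULL) {
  centers <- as.numeric(centers)
  n <- length(centers)
  if (n < 1L) stop("need at least one well")
  if (is.unsorted(centers, strictly = TRUE))
    stop("well centers must be strictly increasing")
  depths <- rep_len(as.numeric(depths), n)
  barriers <- rep_len(as.numeric(barriers), n + 1L)
  if (any(!is.finite(depths)) || any(!is.finite(barriers)))
    stop("landscape energies must be finite")
  if (any(depths < 0)) stop("well depths must be >= 0 (kT below reservoir)")
  if (any(barriers + depths[c(1L, seq_len(n))] <= 0) ||
      any(barriers + depths[c(seq_len(n), n)] <= 0))
    stop("every barrier must lie above its adjacent well minima")
  if (!is.null(names)) {
    names <- as.character(names)
    if (length(names) != n) stop("one name per well required")
  }
  if (kappa < 0) stop("kappa must be >= 0")
  if (is.null(s1_top)) {
    s1_top <- if (!is.null(names) && "S1" %in% names)
      which(names == "S1") else max(n, 1L)
  }
  s1_top <- as.integer(s1_top)
  if (s1_top < 1L || s1_top > n + 1L) stop("s1_top out of range")
  if (!is.null(barrier_halfwidth)) {
    if (barrier_halfwidth <= 0) stop("barrier_halfwidth must be positive")
    if (n > 1L && 2 * barrier_halfwidth >= min(diff(centers)))
      stop("barrier_halfwidth too large for the well spacing")
  }
  if (!is.null(well_halfwidth)) {
    if (is.null(barrier_halfwidth))
      stop("well_halfwidth requires barrier_halfwidth")
    if (well_halfwidth <= 0) stop("well_halfwidth must be positive")
    if (n > 1L &&
        2 * (well_halfwidth + barrier_halfwidth) >= min(diff(centers)))
      stop("well_halfwidth + barrier_halfwidth too large for the well spacing")
  }
  obj <- structure(list(centers = centers, depths = depths,
                        barriers = barriers, names = names, kappa = kappa,
                        s1_top = s1_top, edge_margin = edge_margin,
                        barrier_halfwidth = barrier_halfwidth,
                        well_halfwidth = well_halfwidth),
                   class = "landscape")
  obj$extrema <- landscape_extrema(obj)
  obj
}

## Breakpoint sequence (z, V) for the piecewise-cosine profile.  Default:
## alternating anchor, top, well, top, ..., anchor with tops midway between
## wells.  With barrier_halfwidth set, each crest carries a flat plateau of
## +-halfwidth at its top.
landscape_extrema <- function(ls) {
  n <- length(ls$centers)
  gaps <- if (n > 1L) diff(ls$centers) / 2 else numeric(0)
  half0 <- if (n > 1L) gaps[1L] else 0.15
  halfN <- if (n > 1L) gaps[length(gaps)] else 0.15
  tops_z <- c(ls$centers[1L] - half0,
              if (n > 1L) ls$centers[-n] + gaps,
              ls$centers[n] + halfN)
  if (is.null(ls$barrier_halfwidth)) {
    z <- c(tops_z[1L] - ls$edge_margin,
           as.vector(rbind(tops_z[-length(tops_z)], ls$centers)),
           tops_z[length(tops_z)],
           tops_z[length(tops_z)] + ls$edge_margin)
    V <- c(0,
           as.vector(rbind(ls$barriers[-length(ls$barriers)], -ls$depths)),
           ls$barriers[length(ls$barriers)],
           0)
    return(list(z = z, V = V))
  }
  w <- ls$barrier_halfwidth
  z <- tops_z[1L] - w - ls$edge_margin
  V <- 0
  ww <- ls$well_halfwidth
  for (k in seq_len(n + 1L)) {
    z <- c(z, tops_z[k] - w, tops_z[k] + w)
    V <- c(V, ls$barriers[k], ls$barriers[k])
    if (k <= n) {
      if (is.null(ww)) {
        z <- c(z, ls$centers[k])
        V <- c(V, -ls$depths[k])
      } else {
        z <- c(z, ls$centers[k] - ww, ls$centers[k] + ww)
        V <- c(V, -ls$depths[k], -ls$depths[k])
      }
    }
  }
  z <- c(z, tops_z[n + 1L] + w + ls$edge_margin)
  V <- c(V, 0)
  keep <- !duplicated(z)
  list(z = z[keep], V = V[keep])
}

#' Evaluate a landscape potential
#'
#' @param ls A [landscape_potential()].
#' @param z Coordinates in nm.
#' @return Potential energy in kT (0 in the reservoirs).
#' @export
landscape_energy <- function(ls, z) {
  stopifnot(inherits(ls, "landscape"))
  ex <- ls$extrema
  v <- numeric(length(z))
  seg <- findInterval(z, ex$z)
  inside <- seg >= 1L & seg < length(ex$z)
  s <- (z[inside] - ex$z[seg[inside]]) /
    (ex$z[seg[inside] + 1L] - ex$z[seg[inside]])
  v[inside] <- ex$V[seg[inside]] +
    (ex$V[seg[inside] + 1L] - ex$V[seg[inside]]) * (1 - cos(pi * s)) / 2
  v
}

#' Force from a landscape potential
#'
#' @param ls A [landscape_potential()].
#' @param z Coordinates in nm.
#' @return `-dV/dz` in kT/nm.
#' @export
landscape_force <- function(ls, z) {
  stopifnot(inherits(ls, "landscape"))
  ex <- ls$extrema
  f <- numeric(length(z))
  seg <- findInterval(z, ex$z)
  inside <- seg >= 1L & seg < length(ex$z)
  dz <- ex$z[seg[inside] + 1L] - ex$z[seg[inside]]
  s <- (z[inside] - ex$z[seg[inside]]) / dz
  f[inside] <- -(ex$V[seg[inside] + 1L] - ex$V[seg[inside]]) *
    pi / (2 * dz) * sin(pi * s)
  f
}

#' @export
print.landscape <- function(x, ...) {
  nm <- if (!is.null(x$names)) x$names else paste0("well", seq_along(x$centers))
  cat(sprintf("<landscape> %d wells, kappa = %g kT/kT\n",
              length(x$centers), x$kappa))
  cat(sprintf("  %-5s center %6.3f nm  depth %5.2f kT\n", nm, x$centers, x$depths),
      sep = "")
  cat("  barrier tops (kT):", paste(sprintf("%.2f", x$barriers), collapse = ", "),
      "\n")
  invisible(x)
}

#' Default six-well filter landscape
#'
#' Wells at the centres of Scav, S4..S0 of a [default_site_map()], 3 kT
#' deep with 1.5 kT barrier tops (4.5 kT hop barriers), a reduced-depth
#' cavity well, and the resonance coupling `kappa` on the S2->S1 top.
#'
#' @param sitemap Site map supplying well centres (default
#'   [default_site_map()]).
#' @param depth Well depth in kT (default 3).
#' @param barrier Barrier-top height in kT (default 1.5).
#' @param kappa S1-barrier modulation coupling (default 0).
#' @return A [landscape_potential()].
#' @export
default_landscape <- function(sitemap = default_site_map(), depth = 3,
                              barrier = 1.5, kappa = 0) {
  wells <- c("Scav", "S4", "S3", "S2", "S1", "S0")
  ctr <- site_centers(sitemap)[wells]
  landscape_potential(ctr, depths = c(depth / 2, rep(depth, 5)),
                      barriers = barrier, names = wells, kappa = kappa)
}

#' Lower the S1 barrier by the resonant carbonyl excitation
#'
#' Implements the barrier-mediated coupling: excitation of the carbonyl
#' stretch (mean oscillator energy `osc_energy`, kT) stabilises the S1
#' coordination cage and lowers the barrier for entering S1 by
#' `kappa * osc_energy`.  All other barriers are untouched; `kappa = 0`
#' returns the landscape unchanged.
#'
#' @param ls A [landscape_potential()].
#' @param osc_energy Mean oscillator energy in kT, `>= 0`.
#' @return A new `landscape` with the S1 entry top lowered.
#' @export
modulated_barrier <- function(ls, osc_energy) {
  stopifnot(inherits(ls, "landscape"))
  if (!is.numeric(osc_energy) || length(osc_energy) != 1L ||
      !is.finite(osc_energy) || osc_energy < 0)
    stop("osc_energy must be a single non-negative number (kT)")
  shift <- ls$kappa * osc_energy
  if (shift == 0) return(ls)
  b <- ls$barriers
  i <- ls$s1_top
  b[i] <- b[i] - shift
  n <- length(ls$centers)
  lo <- if (i > 1L) ls$depths[i - 1L] else 0
  hi <- if (i <= n) ls$depths[i] else 0
  if (b[i] + min(lo, hi) <= 0)
    stop("modulation would remove the S1 barrier entirely (",
         signif(b[i], 3), " kT top); reduce kappa or osc_energy")
  landscape_potential(ls$centers, ls$depths, b, names = ls$names,
                      kappa = ls$kappa, s1_top = ls$s1_top,
                      edge_margin = ls$edge_margin,
                      barrier_halfwidth = ls$barrier_halfwidth,
                      well_halfwidth = ls$well_halfwidth)
}

#' Uniformly shift every barrier top
#'
#' Convenience for Arrhenius-type experiments: returns the same landscape
#' with all barrier tops moved by `delta` kT (negative = lowered), leaving
#' the well minima in place so every hop barrier changes by exactly
#' `delta`.
#'
#' @param ls A [landscape_potential()].
#' @param delta Shift in kT applied to every barrier top.
#' @return A new `landscape`.
#' @export
shift_barriers <- function(ls, delta) {
  stopifnot(inherits(ls, "landscape"))
  landscape_potential(ls$centers, ls$depths, ls$barriers + delta,
                      names = ls$names, kappa = ls$kappa,
                      s1_top = ls$s1_top, edge_margin = ls$edge_margin,
                      barrier_halfwidth = ls$barrier_halfwidth,
                      well_halfwidth = ls$well_halfwidth)
}
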