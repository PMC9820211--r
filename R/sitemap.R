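## Site map: ordered half-open intervals along the pore axis naming the
## intracellular reservoir, the cavity site Scav, the filter sites S4..S1,
## the external site S0 and the extracellular reservoir.

SITE_ORDER <- c("intracellular", "Scav", "S4", "S3", "S2", "S1", "S0",
                "extracellular")
SF_SITES <- c("S1", "S2", "S3", "S4")

#' Site map of the pore axis
#'
#' Defines the binding-site geometry as contiguous half-open intervals
#' `[z_lo, z_hi)` ordered from the intracellular side (low z) to the
#' extracellular side (high z).  The four filter sites S4..S1 are mandatory;
#' half-open intervals make every boundary z assignment deterministic.
#'
#' @param name Character vector of region names, a subset of
#'   `c("intracellular", "Scav", "S4", "S3", "S2", "S1", "S0",
#'   "extracellular")` in that order.
#' @param z_lo,z_hi Interval bounds in nm; intervals must tile the axis
#'   contiguously without overlap.
#' @return A `site_map`: a data.frame with columns `name`, `z_lo`, `z_hi`.
#' @seealso [default_site_map()], [site_of()]
#' @export
site_map <- function(name, z_lo, z_hi) {
  name <- as.character(name)
  z_lo <- as.numeric(z_lo); z_hi <- as.numeric(z_hi)
  if (length(name) != length(z_lo) || length(name) != length(z_hi))
    stop("name, z_lo, z_hi must have equal length")
  if (anyDuplicated(name)) stop("site names must be unique")
  bad <- setdiff(name, SITE_ORDER)
  if (length(bad)) stop("unknown site name(s): ", paste(bad, collapse = ", "))
  miss <- setdiff(SF_SITES, name)
  if (length(miss))
    stop("site map must contain the filter sites S4-S1; missing: ",
         paste(miss, collapse = ", "))
  if (is.unsorted(match(name, SITE_ORDER), strictly = TRUE))
    stop("sites must be listed in pore order intracellular -> extracellular")
  o <- order(z_lo)
  if (!identical(o, seq_along(z_lo)))
    stop("z intervals must increase with site order")
  if (any(z_hi <= z_lo)) stop("empty interval: z_hi must exceed z_lo")
  if (length(name) > 1L && any(abs(z_lo[-1L] - z_hi[-length(z_hi)]) > 1e-9))
    stop("intervals must be contiguous (z_lo[i+1] == z_hi[i])")
  structure(data.frame(name = name, z_lo = z_lo, z_hi = z_hi,
                       stringsAsFactors = FALSE),
            class = c("site_map", "data.frame"))
}

#' Default KcsA-like site map
#'
#' Reduced-scale geometry: 0.3 nm-wide binding sites Scav, S4..S0 flanked by
#' reservoirs, spanning a 3 nm box.  Real selectivity-filter sites are
#' 0.23-0.31 nm apart; the default keeps that spacing while leaving each
#' reservoir wide enough (0.6 nm) that a transiting ion is sampled there.
#'
#' @param site_width Width of each binding site in nm (default 0.3).
#' @param reservoir_width Width of each reservoir in nm (default 0.6).
#' @param z0 Lower edge of the intracellular reservoir (default 0).
#' @return A [site_map()] with all eight regions.
#' @export
default_site_map <- function(site_width = 0.3, reservoir_width = 0.6, z0 = 0) {
  widths <- c(reservoir_width, rep(site_width, 6L), reservoir_width)
  hi <- z0 + cumsum(widths)
  lo <- c(z0, hi[-length(hi)])
  site_map(SITE_ORDER, lo, hi)
}

#' Map z coordinates to named regions
#'
#' Each z is assigned to the unique half-open interval containing it;
#' coordinates outside the mapped range clamp to the flanking reservoirs so
#' membership is total.
#'
#' @param z Numeric vector of pore-axis coordinates (nm).
#' @param sitemap A [site_map()].
#' @return Character vector of region names, same length as `z`.
#' @export
site_of <- function(z, sitemap) {
  stopifnot(inherits(sitemap, "site_map"))
  idx <- findInterval(z, sitemap$z_lo)   # 0 = below first interval
  idx[idx < 1L] <- 1L
  idx[idx > nrow(sitemap)] <- nrow(sitemap)
  sitemap$name[idx]
}

#' Interval centre of each region
#' @param sitemap A [site_map()].
#' @return Named numeric vector of interval midpoints (nm).
#' @export
site_centers <- function(sitemap) {
  stats::setNames((sitemap$z_lo + sitemap$z_hi) / 2, sitemap$name)
}

## boundary planes used by the permeation module
entry_plane <- function(sitemap) sitemap$z_hi[sitemap$name == "intracellular"]
exit_plane  <- function(sitemap) sitemap$z_lo[sitemap$name == "extracellular"]
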