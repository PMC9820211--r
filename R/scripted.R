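## Scripted trajectories: deterministic fixtures whose site assignment,
## permeation events and mechanisms are known exactly, used to test the
## occupancy / permeation / mechanism modules against bookkeeping rather
## than against stochastic dynamics.

#' Build a scripted trajectory
#'
#' A script prescribes, segment by segment, which region every particle
#' occupies; the builder emits a trajectory whose frame-wise site
#' assignment reproduces the script exactly.  Each particle is placed at
#' the centre of its region (particles sharing a reservoir are offset
#' deterministically; two particles may not share one binding site).
#'
#' The script is validated for physical consistency: a particle may move by
#' at most one region between consecutive segments, except for the
#' recycling jump extracellular -> intracellular (or the reverse), and two
#' particles inside the pore may not pass through each other.
#'
#' @param script A list with elements:
#'   \describe{
#'     \item{species}{character vector, one `"K"`/`"W"` per particle}
#'     \item{regions}{character matrix, segments x particles, entries from
#'       `c("intracellular","Scav","S4","S3","S2","S1","S0","extracellular")`}
#'     \item{dwell}{integer vector, frames per segment (default 1)}
#'   }
#' @param sitemap A [site_map()]; default [default_site_map()].
#' @param dt_fs Frame spacing in fs (default 1000).
#' @return A [trajectory()] carrying `metadata$script`.
#' @seealso [script_permeation_count()] for the bookkeeping oracle.
#' @export
build_scripted_trajectory <- function(script, sitemap = default_site_map(),
                                      dt_fs = 1000) {
  if (is.null(script$regions) || !length(script$regions))
    stop("empty script: at least one segment is required")
  regions <- as.matrix(script$regions)
  if (!is.character(regions)) regions <- matrix(as.character(regions),
                                                nrow(script$regions))
  species <- as.character(script$species)
  if (ncol(regions) != length(species))
    stop("script needs one region column per particle")
  dwell <- script$dwell
  if (is.null(dwell)) dwell <- rep(1L, nrow(regions))
  dwell <- as.integer(rep_len(dwell, nrow(regions)))
  if (any(dwell < 1L)) stop("dwell times must be >= 1 frame")
  bad <- setdiff(unique(as.vector(regions)), sitemap$name)
  if (length(bad))
    stop("script uses region(s) absent from the site map: ",
         paste(bad, collapse = ", "))
  ord <- match(regions, SITE_ORDER)
  dim(ord) <- dim(regions)
  nseg <- nrow(regions); npart <- ncol(regions)

  ## consistency: single-region moves (allowing the recycling wrap) and no
  ## crossing inside the pore
  if (nseg > 1L) {
    for (s in 2L:nseg) {
      dstep <- abs(ord[s, ] - ord[s - 1L, ])
      wrap <- dstep == length(SITE_ORDER) - 1L
      if (any(dstep > 1L & !wrap))
        stop("inconsistent script at step ", s, ": particle ",
             which(dstep > 1L & !wrap)[1L],
             " jumps over intermediate sites")
      pore_prev <- ord[s - 1L, ] > 1L & ord[s - 1L, ] < length(SITE_ORDER)
      pair <- which(pore_prev)
      if (length(pair) > 1L) {
        for (a in pair) for (b in pair) {
          if (a < b && ord[s - 1L, a] != ord[s - 1L, b] &&
              sign(ord[s, a] - ord[s, b]) ==
              -sign(ord[s - 1L, a] - ord[s - 1L, b]) &&
              ord[s, a] != ord[s, b])
            stop("inconsistent script at step ", s, ": particles ", a,
                 " and ", b, " pass through each other inside the pore")
        }
      }
    }
  }
  ## no shared binding site (reservoirs may hold several particles)
  for (s in seq_len(nseg)) {
    inner <- regions[s, ] %in% setdiff(SITE_ORDER, c("intracellular",
                                                     "extracellular"))
    dup <- regions[s, inner][duplicated(regions[s, inner])]
    if (length(dup))
      stop("inconsistent script at step ", s, ": two particles share site ",
           dup[1L])
  }

  centers <- site_centers(sitemap)
  nfr <- sum(dwell)
  z <- matrix(NA_real_, nfr, npart)
  row0 <- c(0L, cumsum(dwell))
  for (s in seq_len(nseg)) {
    pos <- centers[regions[s, ]]
    for (rn in c("intracellular", "extracellular")) {
      here <- which(regions[s, ] == rn)
      if (length(here) > 1L)
        pos[here] <- pos[here] + (seq_along(here) - 1L) * 0.05 -
          0.05 * (length(here) - 1L) / 2
    }
    z[(row0[s] + 1L):row0[s + 1L], ] <- matrix(pos, dwell[s], npart,
                                               byrow = TRUE)
  }
  trajectory((seq_len(nfr) - 1L) * dt_fs, z, species,
             id = paste0(species, seq_len(npart)),
             box_z = max(sitemap$z_hi) - min(sitemap$z_lo),
             metadata = list(scripted = TRUE),
  )
}

#' Permeation bookkeeping for a script
#'
#' Counts, directly from the region strings (independent of any coordinate
#' or site-assignment logic), how many complete outward transits the script
#' prescribes: a particle that is seen in `intracellular`, later visits at
#' least one filter site, and then reaches `extracellular` before returning
#' to `intracellular`.
#'
#' @param script A script as in [build_scripted_trajectory()].
#' @return data.frame with one row per scripted outward event: `particle`
#'   (column index), `species`, `segment_exit`.
#' @export
script_permeation_count <- function(script) {
  regions <- as.matrix(script$regions)
  species <- as.character(script$species)
  out <- list()
  pore_names <- setdiff(SITE_ORDER, c("intracellular", "extracellular"))
  for (p in seq_len(ncol(regions))) {
    armed <- FALSE; seen_sf <- FALSE
    for (s in seq_len(nrow(regions))) {
      r <- regions[s, p]
      if (r == "intracellular") { armed <- TRUE; seen_sf <- FALSE }
      else if (armed && r %in% pore_names) seen_sf <- TRUE
      else if (r == "extracellular") {
        if (armed && seen_sf)
          out[[length(out) + 1L]] <- data.frame(particle = p,
                                                species = species[p],
                                                segment_exit = s)
        armed <- FALSE; seen_sf <- FALSE
      }
    }
  }
  if (!length(out))
    return(data.frame(particle = integer(0), species = character(0),
                      segment_exit = integer(0)))
  do.call(rbind, out)
}
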