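## Potential of mean force along the pore axis by Boltzmann inversion of
## the equilibrium density: W(z) = -kT ln(rho(z)/rho_max).  Exact for the
## simulator's unbiased equilibrium runs; profiles computed from driven
## (field or voltage) runs are quasi-PMFs and are labelled as such in the
## output metadata.

#' Potential of mean force by Boltzmann inversion
#'
#' Histograms the z samples of one species (after the discard time) on a
#' uniform grid and inverts the density: `W(z) = -ln(rho/rho_max)` in kT.
#' The minimum is referenced to zero; empty bins are flagged (`W = NA`),
#' never interpolated.
#'
#' @param traj A [trajectory()].
#' @param species Species whose density is inverted (default `"K"`).
#' @param z_range Length-2 numeric range in nm (default: the pore span of
#'   `sitemap` when given, otherwise the sampled range).
#' @param bin_width Bin width in nm (default 0.02).
#' @param discard_time_ns Equilibration time excluded (default 0).
#' @param equilibrium Logical flag stored in the profile: `FALSE` marks a
#'   quasi-PMF from a driven run.  Defaults to the absence of field and
#'   voltage entries in the trajectory metadata.
#' @return A `pmf_profile` data.frame: `z_nm` (bin centres), `W_kT`
#'   (min-referenced, `NA` on empty bins), `n_samples`; attributes
#'   `bin_width`, `temperature`, `equilibrium`.
#' @export
compute_pmf <- function(traj, species = "K", z_range = NULL, bin_width = 0.02,
                        discard_time_ns = 0, equilibrium = NULL) {
  stopifnot(inherits(traj, "trajectory"))
  if (bin_width <= 0) stop("bin_width must be positive")
  cols <- which(traj$species %in% species)
  if (!length(cols)) stop("trajectory holds no particle of species ",
                          paste(species, collapse = "/"))
  keep <- traj$times_fs >= discard_time_ns * 1e6
  if (!any(keep)) stop("discard_time removes every frame")
  zs <- as.vector(traj$z[keep, cols])
  if (is.null(z_range)) z_range <- range(zs)
  zs <- zs[zs >= z_range[1L] & zs < z_range[2L]]
  if (!length(zs)) stop("no samples inside z_range after discard")
  brk <- seq(z_range[1L], z_range[2L] + bin_width - 1e-12, by = bin_width)
  cnt <- tabulate(findInterval(zs, brk), nbins = length(brk) - 1L)
  W <- rep(NA_real_, length(cnt))
  W[cnt > 0L] <- -log(cnt[cnt > 0L] / max(cnt))
  W <- W - min(W, na.rm = TRUE)   # reference: global minimum at 0
  if (any(cnt == 0L))
    tz_log("compute_pmf: ", sum(cnt == 0L),
           " empty bin(s) flagged as NA (not interpolated)")
  if (is.null(equilibrium)) {
    md <- traj$metadata
    equilibrium <- !isTRUE((md$E0 %||% 0) > 0) &&
      !isTRUE(abs(md$membrane_voltage %||% 0) > 0)
  }
  structure(data.frame(z_nm = (brk[-length(brk)] + brk[-1L]) / 2,
                       W_kT = W, n_samples = cnt),
            class = c("pmf_profile", "data.frame"),
            bin_width = bin_width,
            temperature = traj$metadata$temperature %||% NA_real_,
            equilibrium = equilibrium)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Per-transition barriers from a PMF profile
#'
#' For each pair of adjacent binding sites present in the profile, locates
#' the well minimum inside each site interval (lowest sampled bin) and
#' reports, for both hop directions, the barrier
#' `max W between the minima - W at the donor minimum`.
#'
#' @param profile A `pmf_profile` covering the filter sites.
#' @param sitemap A [site_map()].
#' @return data.frame with columns `from`, `to`, `barrier_kT`.
#' @export
site_barriers <- function(profile, sitemap) {
  stopifnot(inherits(profile, "pmf_profile"), inherits(sitemap, "site_map"))
  wells <- sitemap[!(sitemap$name %in% c("intracellular", "extracellular")), ]
  idx_min <- W_min <- stats::setNames(numeric(nrow(wells)), wells$name)
  for (i in seq_len(nrow(wells))) {
    sel <- which(profile$z_nm >= wells$z_lo[i] & profile$z_nm < wells$z_hi[i] &
                   !is.na(profile$W_kT))
    if (!length(sel))
      stop("site ", wells$name[i], " has no sampled bins; cannot place its minimum")
    j <- sel[which.min(profile$W_kT[sel])]
    idx_min[i] <- j; W_min[i] <- profile$W_kT[j]
  }
  rows <- list()
  for (i in seq_len(nrow(wells) - 1L)) {
    a <- idx_min[i]; b <- idx_min[i + 1L]
    span <- profile$W_kT[a:b]
    top <- max(span, na.rm = TRUE)
    rows[[length(rows) + 1L]] <- data.frame(
      from = wells$name[i], to = wells$name[i + 1L],
      barrier_kT = top - W_min[i])
    rows[[length(rows) + 1L]] <- data.frame(
      from = wells$name[i + 1L], to = wells$name[i],
      barrier_kT = top - W_min[i + 1L])
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write a PMF profile as TSV
#' @param profile A `pmf_profile`.
#' @param path Output file (`z_nm  W_kT  n_samples`); the header comments
#'   carry bin width and the equilibrium/driven label.
#' @return Invisibly, `path`.
#' @export
write_pmf <- function(profile, path) {
  con <- file(path, "w"); on.exit(close(con))
  writeLines(sprintf("# bin_width_nm = %g", attr(profile, "bin_width")), con)
  writeLines(sprintf("# estimate = %s",
                     if (isTRUE(attr(profile, "equilibrium"))) "equilibrium PMF"
                     else "quasi-PMF (driven run)"), con)
  utils::write.table(profile, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
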