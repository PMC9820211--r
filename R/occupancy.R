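## Selectivity-filter occupancy states: per-frame 4-character codes over
## {K, W, 0} ordered S1 -> S4 (leftmost character = S1, the extracellular
## end of the filter), and their time-weighted census.

#' Assign filter sites frame by frame
#'
#' For every frame each site S1..S4 is labelled `K` if a potassium ion lies
#' in its interval, `W` if a water does, and `0` if it is vacant.  If two
#' particles fall into the same interval in the same frame the one nearer
#' the interval centre wins and a warning is logged (the simulator's
#' single-file exclusion makes this rare).
#'
#' @param traj A [trajectory()].
#' @param sitemap A [site_map()] containing S1..S4.
#' @return An `occupancy_states` data.frame with columns `frame`, `t_fs`,
#'   `code`.
#' @examples
#' sm <- default_site_map()
#' ctr <- site_centers(sm)
#' tr <- trajectory(0, matrix(ctr[c("S1", "S2", "S3", "S4")], 1),
#'                  c("K", "K", "K", "W"), box_z = 3)
#' assign_sites(tr, sm)$code   # "KKKW"
#' @export
assign_sites <- function(traj, sitemap) {
  stopifnot(inherits(traj, "trajectory"))
  if (!inherits(sitemap, "site_map") || !all(SF_SITES %in% sitemap$name))
    stop("site map must define the filter sites S1-S4")
  mobile <- which(traj$species %in% c("K", "W"))
  nfr <- n_frames(traj)
  codes <- matrix("0", nfr, 4L, dimnames = list(NULL, SF_SITES))
  ties <- 0L
  sf <- sitemap[match(SF_SITES, sitemap$name), ]
  for (k in seq_len(4L)) {
    lo <- sf$z_lo[k]; hi <- sf$z_hi[k]; mid <- (lo + hi) / 2
    if (!length(mobile)) next
    zin <- traj$z[, mobile, drop = FALSE]
    inside <- zin >= lo & zin < hi
    hits <- rowSums(inside)
    multi <- which(hits > 1L)
    ties <- ties + length(multi)
    one <- which(hits >= 1L)
    if (length(one)) {
      pick <- vapply(one, function(f) {
        cand <- which(inside[f, ])
        cand[which.min(abs(zin[f, cand] - mid))]
      }, integer(1))
      codes[one, k] <- traj$species[mobile[pick]]
    }
  }
  if (ties > 0L)
    tz_log("assign_sites: ", ties, " frame/site assignment(s) had multiple ",
           "particles in one interval; nearest-to-centre kept")
  structure(data.frame(frame = seq_len(nfr), t_fs = traj$times_fs,
                       code = apply(codes, 1L, paste, collapse = ""),
                       stringsAsFactors = FALSE),
            class = c("occupancy_states", "data.frame"))
}

#' Default tracked occupancy codes
#'
#' The six direct-contact configurations followed in the census (the two
#' dominant ones, `KKKW` and `K0KK`, plus the remaining vacancy/contact
#' arrangements seen during direct knock-on); everything else pools into
#' `"Others"`.
#' @return Character vector of 4-character codes.
#' @export
tracked_codes_default <- function() {
  c("KKKW", "K0KK", "KK0K", "0KKK", "KKK0", "WKKK")
}

#' Occupancy-state census
#'
#' Time-weighted (per-frame) fractions of each tracked code over the frames
#' after `discard_time_ns`; untracked codes are pooled into `"Others"`.
#'
#' @param states An `occupancy_states` from [assign_sites()].
#' @param tracked Codes reported individually (default
#'   [tracked_codes_default()]).
#' @param discard_time_ns Frames before this time are excluded (default 0).
#' @return A `state_census` data.frame with columns `code`, `frames`,
#'   `fraction`; fractions sum to 1.
#' @export
census <- function(states, tracked = tracked_codes_default(),
                   discard_time_ns = 0) {
  stopifnot(inherits(states, "occupancy_states"))
  keep <- states$t_fs >= discard_time_ns * 1e6
  if (!any(keep)) stop("no frames left after discard_time")
  code <- states$code[keep]
  n <- length(code)
  cnt <- table(code)
  tracked_n <- vapply(tracked, function(cd)
    if (cd %in% names(cnt)) as.integer(cnt[[cd]]) else 0L, integer(1))
  others <- n - sum(tracked_n)
  out <- data.frame(code = c(tracked, "Others"),
                    frames = c(tracked_n, others),
                    stringsAsFactors = FALSE)
  out$fraction <- out$frames / n
  structure(out, class = c("state_census", "data.frame"), total_frames = n)
}

#' Write a state census as TSV
#' @param cen A `state_census`.
#' @param path Output file (`code  frames  fraction`).
#' @return Invisibly, `path`.
#' @export
write_census <- function(cen, path) {
  utils::write.table(cen, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
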