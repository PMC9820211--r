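## Pore-radius profiling from symmetric carbonyl-oxygen pairs: the pore
## radius at a residue ring is r = l/2 - r_o, with l the cross-pore
## distance between the two symmetric carbonyl oxygens and r_o the oxygen
## radius (default 1.52 A, the van der Waals radius; the formula's r_o is
## configurable since no single value is canonical).

#' Euclidean distance between two labelled oxygens in one frame
#'
#' @param a,b Length-3 numeric coordinates (x, y, z) in Angstrom.
#' @return Distance in Angstrom.
#' @export
pair_distance <- function(a, b) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) != 3L || length(b) != 3L || anyNA(a) || anyNA(b))
    stop("pair_distance needs complete 3-D coordinates for both atoms")
  sqrt(sum((a - b)^2))
}

#' Pore radius from a cross-pore oxygen-oxygen distance
#'
#' `r = l/2 - r_o`.  A negative radius (overlapping atoms) is returned
#' with a warning and flagged in the `overlap` attribute.
#'
#' @param l Oxygen-oxygen centre distance in Angstrom, `>= 0`.
#' @param r_o Oxygen radius in Angstrom (default 1.52).
#' @return Pore radius in Angstrom (vectorised over `l`).
#' @examples
#' pore_radius(5.84)   # 1.4 A, the filter constriction
#' @export
pore_radius <- function(l, r_o = 1.52) {
  if (any(l < 0)) stop("distance l must be >= 0")
  if (r_o < 0) stop("oxygen radius must be >= 0")
  r <- l / 2 - r_o
  if (any(r < 0))
    warning(sum(r < 0), " radius value(s) negative: oxygen atoms overlap")
  attr(r, "overlap") <- r < 0
  r
}

#' Cross-pore distance and radius time series per residue
#'
#' For each residue, computes the per-frame oxygen-oxygen distance between
#' the labelled symmetric pair (when four oxygens are given, the two
#' diagonal pairs are averaged), the derived radius, a running mean, and
#' the vibration amplitude, operationalised as the standard deviation of
#' `l` after the discard time.  With several replicate trajectories the
#' across-replicate mean series is reported too.
#'
#' @param trajs A [trajectory()] (with `x`, `y` coordinates) or a list of
#'   replicate trajectories with identical labelling.
#' @param pairs Named list: for each residue label (e.g. `"Y78"`), a
#'   character vector of 2 or 4 particle ids of its carbonyl oxygens; with
#'   four ids the first two and last two form the diagonal pairs.
#' @param r_o Oxygen radius in Angstrom (default 1.52).
#' @param smooth_ns Width of the running-mean window in ns (default: no
#'   smoothing beyond the cumulative running mean).
#' @param discard_time_ns Frames before this time are excluded from the
#'   amplitude statistic (default 0).
#' @return A `pore_radius_series`: list with per-residue data.frames
#'   (`t_ns`, `l_A`, `r_A`, `l_run_mean_A`) under `$series` (averaged over
#'   replicates when several are given), and `$summary` (`residue`,
#'   `mean_l_A`, `mean_r_A`, `amplitude_A`).
#' @export
radius_series <- function(trajs, pairs, r_o = 1.52, smooth_ns = NULL,
                          discard_time_ns = 0) {
  if (inherits(trajs, "trajectory")) trajs <- list(trajs)
  if (!length(trajs)) stop("no trajectories given")
  ids0 <- trajs[[1L]]$id
  for (tr in trajs) {
    if (!inherits(tr, "trajectory")) stop("trajs must contain trajectory objects")
    if (is.null(tr$x) || is.null(tr$y))
      stop("radius_series needs 3-D coordinates (x, y present)")
    if (!identical(tr$id, ids0))
      stop("inconsistent particle labelling across replicate trajectories")
  }
  series <- list(); summary_rows <- list()
  for (res in names(pairs)) {
    idp <- pairs[[res]]
    if (!all(idp %in% ids0))
      stop("missing atom(s) for residue ", res, ": ",
           paste(setdiff(idp, ids0), collapse = ", "))
    if (!length(idp) %in% c(2L, 4L))
      stop("residue ", res, " needs 2 or 4 oxygen ids")
    per_rep <- lapply(trajs, function(tr) {
      cols <- match(idp, tr$id)
      dist2 <- function(i, j)
        sqrt((tr$x[, i] - tr$x[, j])^2 + (tr$y[, i] - tr$y[, j])^2 +
               (tr$z[, i] - tr$z[, j])^2) * 10   # nm -> Angstrom
      l <- if (length(idp) == 2L) dist2(cols[1L], cols[2L])
      else (dist2(cols[1L], cols[2L]) + dist2(cols[3L], cols[4L])) / 2
      l
    })
    l_mean <- Reduce(`+`, per_rep) / length(per_rep)
    t_ns <- trajs[[1L]]$times_fs * 1e-6
    run_mean <- cumsum(l_mean) / seq_along(l_mean)
    if (!is.null(smooth_ns)) {
      k <- max(1L, round(smooth_ns / max(diff(t_ns)[1L], 1e-12)))
      if (k > 1L && k <= length(l_mean)) {
        sm <- stats::filter(l_mean, rep(1 / k, k), sides = 2)
        run_mean <- as.numeric(ifelse(is.na(sm), run_mean, sm))
      }
    }
    r <- suppressWarnings(pore_radius(l_mean, r_o))
    series[[res]] <- data.frame(t_ns = t_ns, l_A = l_mean,
                                r_A = as.numeric(r), l_run_mean_A = run_mean)
    keep <- t_ns >= discard_time_ns
    summary_rows[[res]] <- data.frame(
      residue = res,
      mean_l_A = mean(l_mean[keep]),
      mean_r_A = mean(l_mean[keep]) / 2 - r_o,
      amplitude_A = stats::sd(l_mean[keep]))
  }
  structure(list(series = series,
                 summary = do.call(rbind, c(summary_rows,
                                            make.row.names = FALSE))),
            class = "pore_radius_series")
}

#' @export
print.pore_radius_series <- function(x, ...) {
  cat("<pore_radius_series>\n")
  print(x$summary)
  invisible(x)
}

#' Write a radius series as TSV
#' @param rs A `pore_radius_series`.
#' @param dir Output directory; one `<residue>_radius.tsv` per residue
#'   (`t_ns  l_A  r_A`) plus `radius_summary.tsv`.
#' @return Invisibly, `dir`.
#' @export
write_radius_series <- function(rs, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (res in names(rs$series))
    utils::write.table(rs$series[[res]],
                       file.path(dir, paste0(res, "_radius.tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(rs$summary, file.path(dir, "radius_summary.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}
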