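## Permeation events, flux and current.  An outward event requires entering
## from the intracellular reservoir, visiting the filter, and crossing into
## the extracellular reservoir without re-crossing the entry plane: a
## two-plane (committor-style) rule that is immune to rapid recrossing noise
## at a single counting plane and to the recycling jump at the box edge.

#' Detect complete permeation events
#'
#' Scans each ion's region sequence (from [site_of()]).  An outward event
#' is opened when the ion sits in the intracellular reservoir, confirmed
#' once it visits at least one binding site, and closed at the first frame
#' in the extracellular reservoir; returning to the intracellular reservoir
#' aborts the attempt.  Inward events are the mirror image.  The recycling
#' jump (extracellular end -> intracellular end between two frames) skips
#' the binding sites entirely and therefore never fakes an event.
#'
#' @param traj A [trajectory()].
#' @param sitemap A [site_map()] with both reservoirs.
#' @param species Species to track (default `"K"`).
#' @return A `permeation_events` data.frame: `ion`, `t_entry_ns` (first
#'   binding-site entry of the transit), `t_exit_ns` (first frame beyond
#'   the far plane), `direction` (`"outward"`/`"inward"`), `mechanism`
#'   (`"unassigned"`; see [classify_event()]).  Zero rows when nothing
#'   permeates.
#' @export
detect_permeations <- function(traj, sitemap, species = "K") {
  stopifnot(inherits(traj, "trajectory"), inherits(sitemap, "site_map"))
  if (!all(c("intracellular", "extracellular") %in% sitemap$name))
    stop("site map must include both reservoirs for event counting")
  ions <- which(traj$species %in% species)
  pore_names <- setdiff(SITE_ORDER, c("intracellular", "extracellular"))
  rows <- list()
  for (j in ions) {
    reg <- site_of(traj$z[, j], sitemap)
    state <- 0L   # 0 idle, +1 outward attempt, -1 inward attempt
    seen_sf <- FALSE; t_entry <- NA_real_
    for (f in seq_along(reg)) {
      r <- reg[f]
      if (r == "intracellular") {
        if (state == -1L && seen_sf) {
          rows[[length(rows) + 1L]] <- data.frame(
            ion = traj$id[j], t_entry_ns = t_entry,
            t_exit_ns = traj$times_fs[f] * 1e-6, direction = "inward",
            mechanism = "unassigned", stringsAsFactors = FALSE)
        }
        state <- 1L; seen_sf <- FALSE; t_entry <- NA_real_
      } else if (r == "extracellular") {
        if (state == 1L && seen_sf) {
          rows[[length(rows) + 1L]] <- data.frame(
            ion = traj$id[j], t_entry_ns = t_entry,
            t_exit_ns = traj$times_fs[f] * 1e-6, direction = "outward",
            mechanism = "unassigned", stringsAsFactors = FALSE)
        }
        state <- -1L; seen_sf <- FALSE; t_entry <- NA_real_
      } else if (state != 0L && r %in% pore_names) {
        if (!seen_sf) t_entry <- traj$times_fs[f] * 1e-6
        seen_sf <- TRUE
      }
    }
  }
  ev <- if (length(rows)) do.call(rbind, rows) else
    data.frame(ion = character(0), t_entry_ns = numeric(0),
               t_exit_ns = numeric(0), direction = character(0),
               mechanism = character(0), stringsAsFactors = FALSE)
  ev <- ev[order(ev$t_exit_ns), , drop = FALSE]
  rownames(ev) <- NULL
  structure(ev, class = c("permeation_events", "data.frame"))
}

#' Flux and ion current from detected events
#'
#' Events closing before `discard_time_ns` are excluded.  The reported
#' current is net outward: `I = (N_out - N_in) * e / T` converted to pA.
#'
#' @param events A `permeation_events` from [detect_permeations()].
#' @param traj The analysed [trajectory()] (supplies the duration).
#' @param discard_time_ns Equilibration time excluded from the statistics
#'   (default 0).
#' @param window_ns Width of the windows for the cumulative flux series
#'   (default: a tenth of the analysed span).
#' @return A `current_result`: list with `n_outward`, `n_inward`, `n_net`,
#'   `duration_ns`, `flux_per_ns` (net), `current_pA` and `window` (a
#'   data.frame `t_ns`, `cum_events`, `flux_per_ns` suitable for
#'   cumulative-flux plots).
#' @export
compute_current <- function(events, traj, discard_time_ns = 0,
                            window_ns = NULL) {
  stopifnot(inherits(events, "permeation_events"), inherits(traj, "trajectory"))
  t_end <- traj$times_fs[n_frames(traj)] * 1e-6
  t0 <- traj$times_fs[1L] * 1e-6
  T_ns <- t_end - max(t0, discard_time_ns)
  if (T_ns <= 0) stop("zero analysed duration: discard_time exceeds the trajectory")
  ev <- events[events$t_exit_ns >= discard_time_ns, , drop = FALSE]
  n_out <- sum(ev$direction == "outward")
  n_in <- sum(ev$direction == "inward")
  n_net <- n_out - n_in
  flux <- n_net / T_ns
  current_pA <- n_net * CONST$e_C / (T_ns * 1e-9) * 1e12
  if (is.null(window_ns)) window_ns <- T_ns / 10
  brk <- seq(max(t0, discard_time_ns), t_end, by = window_ns)
  if (brk[length(brk)] < t_end) brk <- c(brk, t_end)
  out_t <- ev$t_exit_ns[ev$direction == "outward"]
  in_t <- ev$t_exit_ns[ev$direction == "inward"]
  counts <- vapply(seq_len(length(brk) - 1L), function(i)
    sum(out_t < brk[i + 1L]) - sum(in_t < brk[i + 1L]), numeric(1))
  win <- data.frame(t_ns = brk[-1L], cum_events = counts,
                    flux_per_ns = counts / (brk[-1L] - brk[1L]))
  structure(list(n_outward = n_out, n_inward = n_in, n_net = n_net,
                 duration_ns = T_ns, flux_per_ns = flux,
                 current_pA = current_pA, window = win),
            class = "current_result")
}

#' @export
print.current_result <- function(x, ...) {
  cat(sprintf("<current_result> %d outward - %d inward = %d events in %.4g ns\n",
              x$n_outward, x$n_inward, x$n_net, x$duration_ns))
  cat(sprintf("  flux = %.4g events/ns, current = %.4g pA\n",
              x$flux_per_ns, x$current_pA))
  invisible(x)
}

#' Ratio of two ion currents
#'
#' @param a,b `current_result` objects; `b` is the reference (e.g. the
#'   no-field condition) and must carry a nonzero current.
#' @return `a$current_pA / b$current_pA`.
#' @export
current_ratio <- function(a, b) {
  stopifnot(inherits(a, "current_result"), inherits(b, "current_result"))
  if (b$current_pA == 0) stop("reference current is zero; ratio undefined")
  a$current_pA / b$current_pA
}

#' Write permeation events as TSV
#' @param events A `permeation_events`.
#' @param path Output file
#'   (`ion_id  t_entry_ns  t_exit_ns  direction  mechanism`).
#' @return Invisibly, `path`.
#' @export
write_events <- function(events, path) {
  out <- events
  names(out)[names(out) == "ion"] <- "ion_id"
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
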