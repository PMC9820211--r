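## Knock-on mechanism classification.  A permeation event is "soft" when,
## throughout its transit window, every pair of neighbouring ions in the
## filter is separated by at least one water (water-mediated conduction);
## it is "direct" when any frame shows two neighbouring ions with no water
## between them.  A vacancy between two ions still counts as direct
## contact: nothing screens the Coulomb repulsion (a declared,
## testable choice matching the vacancy-bearing contact states such as
## K0KK).  Events whose window never holds two ions are unassigned.

## per-code helper: is every adjacent ion pair in the S1..S4 string
## separated by >= 1 water?  Returns NA when < 2 ions.
code_water_separated <- function(code) {
  ch <- strsplit(code, "")[[1L]]
  kpos <- which(ch == "K")
  if (length(kpos) < 2L) return(NA)
  for (i in seq_len(length(kpos) - 1L)) {
    if (kpos[i + 1L] - kpos[i] == 1L) return(FALSE)
    between <- ch[(kpos[i] + 1L):(kpos[i + 1L] - 1L)]
    if (!any(between == "W")) return(FALSE)
  }
  TRUE
}

#' Classify one permeation event as direct or soft knock-on
#'
#' @param event One row of a `permeation_events` data.frame.
#' @param states An `occupancy_states` covering the event window
#'   `[t_entry, t_exit]`.
#' @return `"soft"`, `"direct"` or `"unassigned"`.
#' @examples
#' # a K-W-K-W filter is water-separated (soft); K-K contact is direct
#' @export
classify_event <- function(event, states) {
  stopifnot(inherits(states, "occupancy_states"))
  t_lo <- event$t_entry_ns * 1e6
  t_hi <- event$t_exit_ns * 1e6
  if (is.na(t_lo)) t_lo <- t_hi
  if (t_lo < min(states$t_fs) - 1e-6 || t_hi > max(states$t_fs) + 1e-6)
    stop("occupancy states do not cover the event window [",
         t_lo, ", ", t_hi, "] fs")
  win <- states$code[states$t_fs >= t_lo & states$t_fs <= t_hi]
  sep <- vapply(win, code_water_separated, NA)
  if (all(is.na(sep))) return("unassigned")
  if (any(!sep, na.rm = TRUE)) "direct" else "soft"
}

#' Mechanism census over a set of events
#'
#' Classifies every event and reports soft/direct percentages over the
#' assigned events, rounded half-up to two decimals for reporting (raw
#' values are kept alongside).
#'
#' @param events A `permeation_events` from [detect_permeations()].
#' @param states An `occupancy_states` covering all event windows.
#' @return A `mechanism_census`: list with `n_direct`, `n_soft`,
#'   `n_unassigned`, `soft_pct`, `direct_pct` (rounded to 2 decimals),
#'   `soft_pct_raw`, `direct_pct_raw` and the per-event `mechanism`
#'   vector.
#' @export
mechanism_census <- function(events, states) {
  stopifnot(inherits(events, "permeation_events"))
  if (!nrow(events)) stop("no events to classify")
  mech <- vapply(seq_len(nrow(events)), function(i)
    classify_event(events[i, ], states), character(1))
  n_soft <- sum(mech == "soft"); n_direct <- sum(mech == "direct")
  n_un <- sum(mech == "unassigned")
  n_assigned <- n_soft + n_direct
  if (n_assigned == 0L)
    stop("zero assigned events: every window held at most one ion")
  soft_raw <- 100 * n_soft / n_assigned
  direct_raw <- 100 * n_direct / n_assigned
  structure(list(n_direct = n_direct, n_soft = n_soft, n_unassigned = n_un,
                 soft_pct = round_half_up(soft_raw, 2L),
                 direct_pct = round_half_up(direct_raw, 2L),
                 soft_pct_raw = soft_raw, direct_pct_raw = direct_raw,
                 mechanism = mech),
            class = "mechanism_census")
}

## round half away from zero (commercial rounding), unlike base round()'s
## round-half-even
round_half_up <- function(x, digits = 0L) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

#' @export
print.mechanism_census <- function(x, ...) {
  cat(sprintf("<mechanism_census> %d direct (%.2f%%), %d soft (%.2f%%), %d unassigned\n",
              x$n_direct, x$direct_pct, x$n_soft, x$soft_pct, x$n_unassigned))
  invisible(x)
}

#' Write per-event mechanisms as TSV
#' @param events A `permeation_events`.
#' @param cen The matching `mechanism_census`.
#' @param path Output file.
#' @return Invisibly, `path`.
#' @export
write_mechanisms <- function(events, cen, path) {
  out <- events
  out$mechanism <- cen$mechanism
  names(out)[names(out) == "ion"] <- "ion_id"
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
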