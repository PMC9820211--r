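## Comparative experiment driver: run the full pipeline (simulate ->
## occupancy -> permeation -> mechanism -> pmf -> geometry proxy) for a set
## of field conditions (e.g. no-field vs 50 vs 51.87 vs 53 THz) and tabulate
## currents, current ratios against the reference condition, knock-on
## percentages and per-site barriers.

#' Experiment plan
#'
#' @param conditions A list; each element a list with `label` (unique
#'   character), `field` (a [field_spec()]), optional `kappa` overriding
#'   the landscape coupling for that condition.
#' @param config Shared [run_config()] (per-condition seeds are derived
#'   from `config$seed` and must stay unique).
#' @param landscape Base [landscape_potential()].
#' @param n_replicates Replicates per condition (default 2); replicate r of
#'   condition c runs with seed `config$seed + 1000*c + r`.
#' @param n_ions,n_waters Particle counts passed to [simulate_channel()].
#' @param reference Label of the condition used as the current-ratio
#'   denominator (default: the first condition).
#' @return An `experiment_plan` object.
#' @export
experiment_plan <- function(conditions, config = run_config(),
                            landscape = default_landscape(),
                            n_replicates = 2L, n_ions = 3L, n_waters = 3L,
                            reference = NULL) {
  labels <- vapply(conditions, `[[`, "", "label")
  if (anyDuplicated(labels)) stop("condition labels must be unique")
  for (cd in conditions)
    if (!inherits(cd$field, "field_spec"))
      stop("condition '", cd$label, "' lacks a field_spec")
  if (is.null(reference)) reference <- labels[1L]
  if (!reference %in% labels) stop("reference label not among conditions")
  structure(list(conditions = conditions, config = config,
                 landscape = landscape,
                 n_replicates = as.integer(n_replicates),
                 n_ions = as.integer(n_ions), n_waters = as.integer(n_waters),
                 reference = reference),
            class = "experiment_plan")
}

#' Run a comparative experiment end to end
#'
#' For every condition and replicate: simulate, assign occupancy states,
#' detect permeations, classify mechanisms, compute the (quasi-)PMF and
#' extract per-site barriers.  Currents are averaged over replicates;
#' ratios are taken against the reference condition.  All seeds and the
#' shared configuration are echoed into the returned bundle.  A failing
#' stage is recorded per condition and flagged in `$failures` instead of
#' aborting the whole run.
#'
#' @param plan An [experiment_plan()].
#' @param out_dir Optional directory; when given, per-condition TSVs
#'   (events, census, PMF) and the cross-condition `report.tsv` +
#'   `report.txt` are written there.
#' @return An `experiment_report`: list with `table` (one row per
#'   condition: mean current, ratio vs reference, soft/direct percentages,
#'   S2->S1 barrier), `per_condition` (full per-replicate objects),
#'   `failures`, `plan`.
#' @export
run_experiment <- function(plan, out_dir = NULL) {
  stopifnot(inherits(plan, "experiment_plan"))
  cfg0 <- plan$config
  rows <- list(); per_cond <- list(); failures <- list()
  for (ci in seq_along(plan$conditions)) {
    cd <- plan$conditions[[ci]]
    tz_log("run_experiment: condition '", cd$label, "'")
    ls_c <- plan$landscape
    if (!is.null(cd$kappa))
      ls_c <- landscape_potential(ls_c$centers, ls_c$depths, ls_c$barriers,
                                  names = ls_c$names, kappa = cd$kappa,
                                  s1_top = ls_c$s1_top,
                                  edge_margin = ls_c$edge_margin)
    reps <- list()
    res_c <- tryCatch({
      for (r in seq_len(plan$n_replicates)) {
        cfg <- cfg0
        cfg$field <- cd$field
        cfg$seed <- cfg0$seed + 1000L * ci + r
        cfg <- validate_run_config(cfg)
        sim <- simulate_channel(cfg, ls_c, plan$n_ions, plan$n_waters)
        states <- assign_sites(sim$trajectory, cfg$sitemap)
        ev <- detect_permeations(sim$trajectory, cfg$sitemap)
        cur <- compute_current(ev, sim$trajectory,
                               discard_time_ns = cfg$discard_time_ns)
        mech <- if (nrow(ev)) tryCatch(mechanism_census(ev, states),
                                       error = function(e) NULL) else NULL
        pmf <- tryCatch(compute_pmf(sim$trajectory,
                                    discard_time_ns = cfg$discard_time_ns,
                                    z_range = c(min(cfg$sitemap$z_lo),
                                                max(cfg$sitemap$z_hi))),
                        error = function(e) NULL)
        bar <- if (!is.null(pmf)) tryCatch(site_barriers(pmf, cfg$sitemap),
                                           error = function(e) NULL) else NULL
        reps[[r]] <- list(seed = cfg$seed, sim = sim, states = states,
                          events = ev, current = cur, mechanism = mech,
                          pmf = pmf, barriers = bar)
      }
      reps
    }, error = function(e) e)
    if (inherits(res_c, "error")) {
      failures[[cd$label]] <- conditionMessage(res_c)
      next
    }
    per_cond[[cd$label]] <- res_c
    cur_mean <- mean(vapply(res_c, function(x) x$current$current_pA, 0))
    softs <- vapply(res_c, function(x)
      if (!is.null(x$mechanism)) x$mechanism$soft_pct_raw else NA_real_, 0)
    s1bar <- vapply(res_c, function(x) {
      if (is.null(x$barriers)) return(NA_real_)
      hit <- x$barriers$from == "S2" & x$barriers$to == "S1"
      if (any(hit)) x$barriers$barrier_kT[hit] else NA_real_
    }, 0)
    rows[[cd$label]] <- data.frame(
      label = cd$label, f_thz = cd$field$f, E0 = cd$field$E0,
      kappa = ls_c$kappa,
      n_replicates = plan$n_replicates,
      seeds = paste(vapply(res_c, function(x) x$seed, 0L), collapse = ","),
      current_pA = cur_mean,
      soft_pct = mean(softs, na.rm = TRUE),
      barrier_S2_S1_kT = mean(s1bar, na.rm = TRUE))
  }
  tab <- do.call(rbind, c(rows, make.row.names = FALSE))
  if (!is.null(tab) && plan$reference %in% tab$label) {
    ref <- tab$current_pA[tab$label == plan$reference]
    tab$current_ratio <- if (ref != 0) tab$current_pA / ref else NA_real_
  }
  rep_obj <- structure(list(table = tab, per_condition = per_cond,
                            failures = failures, plan = plan),
                       class = "experiment_report")
  if (!is.null(out_dir)) write_experiment_report(rep_obj, out_dir)
  rep_obj
}

#' @export
print.experiment_report <- function(x, ...) {
  cat("<experiment_report>\n")
  if (!is.null(x$table)) print(x$table[, c("label", "f_thz", "current_pA",
                                           "current_ratio", "soft_pct")])
  if (length(x$failures)) {
    cat("failures:\n")
    for (lb in names(x$failures)) cat("  ", lb, ": ", x$failures[[lb]], "\n")
  }
  invisible(x)
}

write_experiment_report <- function(rep, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!is.null(rep$table))
    utils::write.table(rep$table, file.path(out_dir, "report.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  for (lb in names(rep$per_condition)) {
    cdir <- file.path(out_dir, gsub("[^A-Za-z0-9_.-]", "_", lb))
    dir.create(cdir, showWarnings = FALSE, recursive = TRUE)
    reps <- rep$per_condition[[lb]]
    for (r in seq_along(reps)) {
      write_events(reps[[r]]$events,
                   file.path(cdir, sprintf("events_rep%d.tsv", r)))
      if (!is.null(reps[[r]]$pmf))
        write_pmf(reps[[r]]$pmf, file.path(cdir, sprintf("pmf_rep%d.tsv", r)))
    }
  }
  con <- file(file.path(out_dir, "report.txt"), "w")
  on.exit(close(con))
  writeLines("thzchannel comparative experiment", con)
  writeLines(utils::capture.output(print(rep$plan$config)), con)
  if (!is.null(rep$table))
    writeLines(utils::capture.output(print(rep$table)), con)
  if (length(rep$failures))
    writeLines(c("failures:", paste0("  ", names(rep$failures), ": ",
                                     unlist(rep$failures))), con)
  invisible(out_dir)
}
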