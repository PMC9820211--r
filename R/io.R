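## Readers and writers: columnar trajectory format, MODEL-separated PDB
## snapshot series, and two-column dipole traces.
##
## Columnar dialect: one row per (frame, particle),
##   t_fs  particle_id  species  z_nm  [x_nm  y_nm]
## tab-separated, '#' starts a comment.  Header comments carry box_z and
## metadata so a round trip is lossless to the printed precision.

#' Read a trajectory file
#'
#' @param path Input file.
#' @param format `"columnar"` (tab-separated, one row per frame/particle)
#'   or `"pdb"` (MODEL-separated snapshot series, coordinates in Angstrom).
#' @return A [trajectory()].
#' @seealso [write_trajectory()] for the dialect definitions.
#' @export
read_trajectory <- function(path, format = c("columnar", "pdb")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("trajectory file not found: ", path)
  traj <- switch(format,
                 columnar = read_traj_columnar(path),
                 pdb = read_traj_pdb(path))
  tz_log(sprintf("read_trajectory: %d frames, %d particles (%s) from %s",
                 n_frames(traj), length(traj$id),
                 paste(sprintf("%s=%d", names(table(traj$species)),
                               as.integer(table(traj$species))), collapse = " "),
                 path))
  traj
}

read_traj_columnar <- function(path) {
  lines <- readLines(path)
  box_z <- NA_real_
  meta <- list()
  hdr <- grep("^#", lines, value = TRUE)
  for (h in hdr) {
    kv <- regmatches(h, regexec("^#\\s*(\\w+)\\s*=\\s*(.*)$", h))[[1L]]
    if (length(kv) == 3L) {
      if (kv[2L] == "box_z") box_z <- as.numeric(kv[3L])
      else meta[[kv[2L]]] <- utils::type.convert(kv[3L], as.is = TRUE)
    }
  }
  body_idx <- which(!grepl("^\\s*(#|$)", lines))
  if (!length(body_idx)) stop("no data rows in ", path)
  fields <- strsplit(lines[body_idx], "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf != 4L & nf != 6L)) {
    bad <- body_idx[which(nf != 4L & nf != 6L)[1L]]
    stop("parse error at line ", bad, " of ", path,
         ": expected 4 or 6 tab-separated fields, got ", nf[which(nf != 4L & nf != 6L)[1L]])
  }
  if (length(unique(nf)) != 1L)
    stop("parse error in ", path, ": mixed 4- and 6-column rows")
  has_xy <- nf[1L] == 6L
  m <- do.call(rbind, fields)
  t_fs <- suppressWarnings(as.numeric(m[, 1L]))
  z    <- suppressWarnings(as.numeric(m[, 4L]))
  if (anyNA(t_fs) || anyNA(z)) {
    bad <- body_idx[which(is.na(t_fs) | is.na(z))[1L]]
    stop("parse error at line ", bad, " of ", path, ": non-numeric coordinate")
  }
  pid <- m[, 2L]; spc <- m[, 3L]
  times <- sort(unique(t_fs))
  ids <- unique(pid)
  fi <- match(t_fs, times); pi <- match(pid, ids)
  zm <- matrix(NA_real_, length(times), length(ids),
               dimnames = list(NULL, ids))
  zm[cbind(fi, pi)] <- z
  if (anyNA(zm)) {
    miss <- which(is.na(zm), arr.ind = TRUE)[1L, ]
    stop("gap error in ", path, ": particle '", ids[miss[2L]],
         "' has no coordinate at t = ", times[miss[1L]], " fs")
  }
  xm <- ym <- NULL
  if (has_xy) {
    xv <- suppressWarnings(as.numeric(m[, 5L]))
    yv <- suppressWarnings(as.numeric(m[, 6L]))
    xm <- zm; xm[] <- NA_real_; ym <- xm
    xm[cbind(fi, pi)] <- xv; ym[cbind(fi, pi)] <- yv
  }
  sp_by_id <- spc[match(ids, pid)]
  if (is.na(box_z)) box_z <- max(zm) + 0.1
  trajectory(times, zm, sp_by_id, id = ids, x = xm, y = ym,
             box_z = box_z, metadata = meta)
}

#' Write a trajectory file
#'
#' The columnar writer stores coordinates in nm with 6 decimals plus
#' `box_z` and scalar metadata in header comments.  The PDB writer emits
#' one `MODEL` per frame with coordinates converted from nm to Angstrom
#' (the internal unit is always nm; Angstrom appears only at the PDB
#' boundary) and the frame spacing in a `REMARK 250` line.
#'
#' @param traj A [trajectory()] with at least one particle.
#' @param path Output file.
#' @param format `"columnar"` or `"pdb"`.
#' @return Invisibly, `path`.
#' @export
write_trajectory <- function(traj, path, format = c("columnar", "pdb")) {
  format <- match.arg(format)
  stopifnot(inherits(traj, "trajectory"))
  if (length(traj$id) == 0L) stop("nothing to write: trajectory has no particles")
  ok <- tryCatch({ con <- file(path, "w"); close(con); TRUE },
                 error = function(e) FALSE)
  if (!ok) stop("cannot write to path: ", path)
  switch(format,
         columnar = write_traj_columnar(traj, path),
         pdb = write_traj_pdb(traj, path))
  invisible(path)
}

write_traj_columnar <- function(traj, path) {
  con <- file(path, "w"); on.exit(close(con))
  writeLines("# thzchannel columnar trajectory: t_fs\tparticle_id\tspecies\tz_nm[\tx_nm\ty_nm]", con)
  writeLines(sprintf("# box_z = %.6f", traj$box_z), con)
  for (key in names(traj$metadata)) {
    v <- traj$metadata[[key]]
    if (is.atomic(v) && length(v) == 1L)
      writeLines(sprintf("# %s = %s", key, format(v, digits = 12)), con)
  }
  nfr <- n_frames(traj); npt <- length(traj$id)
  t_col <- rep(traj$times_fs, each = npt)
  id_col <- rep(traj$id, times = nfr)
  sp_col <- rep(traj$species, times = nfr)
  z_col <- as.vector(t(traj$z))
  if (!is.null(traj$x)) {
    rows <- sprintf("%.6f\t%s\t%s\t%.6f\t%.6f\t%.6f", t_col, id_col, sp_col,
                    z_col, as.vector(t(traj$x)), as.vector(t(traj$y)))
  } else {
    rows <- sprintf("%.6f\t%s\t%s\t%.6f", t_col, id_col, sp_col, z_col)
  }
  writeLines(rows, con)
}

## PDB boundary.  Species map to element/residue names; particle order is
## preserved so ids survive a round trip via atom serial numbers.
pdb_resid <- c(K = "POT", W = "SOL", O = "CAR", CL = "CLA")

write_traj_pdb <- function(traj, path) {
  con <- file(path, "w"); on.exit(close(con))
  writeLines(sprintf("REMARK 250 DT_FS %.9f T0_FS %.9f BOX_Z_NM %.6f",
                     if (is.na(frame_dt(traj))) 0 else frame_dt(traj),
                     traj$times_fs[1L], traj$box_z), con)
  writeLines(paste0("REMARK 250 IDS ", paste(traj$id, collapse = " ")), con)
  npt <- length(traj$id)
  elety <- ifelse(traj$species == "CL", "CL",
                  ifelse(traj$species == "W", "OW", traj$species))
  for (f in seq_len(n_frames(traj))) {
    writeLines(sprintf("MODEL     %4d", f), con)
    xs <- if (!is.null(traj$x)) traj$x[f, ] * 10 else rep(0, npt)
    ys <- if (!is.null(traj$y)) traj$y[f, ] * 10 else rep(0, npt)
    writeLines(sprintf("ATOM  %5d %-4s %-4s%5d    %8.3f%8.3f%8.3f  1.00  0.00",
                       seq_len(npt), elety, pdb_resid[traj$species],
                       seq_len(npt), xs, ys, traj$z[f, ] * 10), con)
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
}

read_traj_pdb <- function(path) {
  lines <- readLines(path)
  rem <- grep("^REMARK 250 DT_FS", lines, value = TRUE)
  dt_fs <- 1; t0 <- 0; box_z <- NA_real_
  if (length(rem)) {
    tok <- strsplit(rem[1L], "\\s+")[[1L]]
    dt_fs <- as.numeric(tok[4L]); t0 <- as.numeric(tok[6L])
    box_z <- as.numeric(tok[8L])
  }
  idrem <- grep("^REMARK 250 IDS ", lines, value = TRUE)
  ids <- if (length(idrem))
    strsplit(sub("^REMARK 250 IDS ", "", idrem[1L]), " ")[[1L]] else NULL
  pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
  xyz <- pdb$xyz                       # frames x (3*natom), Angstrom
  if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1L)
  natom <- ncol(xyz) / 3L
  resid1 <- pdb$atom$resid[seq_len(natom)]
  species <- names(pdb_resid)[match(resid1, pdb_resid)]
  if (anyNA(species))
    stop("parse error in ", path, ": unknown residue name(s) ",
         paste(unique(resid1[is.na(species)]), collapse = ", "))
  zm <- xyz[, seq(3L, ncol(xyz), by = 3L), drop = FALSE] / 10
  xm <- xyz[, seq(1L, ncol(xyz), by = 3L), drop = FALSE] / 10
  ym <- xyz[, seq(2L, ncol(xyz), by = 3L), drop = FALSE] / 10
  nfr <- nrow(zm)
  times <- t0 + (seq_len(nfr) - 1L) * (if (dt_fs > 0) dt_fs else 1)
  if (is.na(box_z)) box_z <- max(zm) + 0.1
  trajectory(times, zm, species, id = ids, x = xm, y = ym, box_z = box_z)
}

#' Write a dipole trace
#'
#' Two-column tab-separated file `t_fs  mu` with a comment header.
#'
#' @param trace A [dipole_trace()].
#' @param path Output file.
#' @return Invisibly, `path`.
#' @export
write_dipole_trace <- function(trace, path) {
  stopifnot(inherits(trace, "dipole_trace"))
  con <- file(path, "w"); on.exit(close(con))
  writeLines("# thzchannel dipole trace: t_fs\tmu", con)
  writeLines(sprintf("%.6f\t%.9g", trace$t_fs, trace$mu), con)
  invisible(path)
}

#' Read a dipole trace
#'
#' @param path Two-column `t_fs  mu` file ('#' comments allowed).
#' @return A [dipole_trace()].
#' @export
read_dipole_trace <- function(path) {
  if (!file.exists(path)) stop("dipole trace file not found: ", path)
  d <- utils::read.table(path, comment.char = "#", col.names = c("t_fs", "mu"))
  dipole_trace(d$t_fs, d$mu)
}
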