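## Trajectory container: time-ordered frames of labelled particles on the
## pore axis.  Frames x particles coordinate matrices, nm / fs units.

SPECIES_ALPHABET <- c("K", "W", "O", "CL")

#' Particle trajectory along the pore axis
#'
#' Construct the container every analysis module consumes: a set of labelled
#' particles (potassium ions `K`, waters `W`, carbonyl oxygens `O`, chloride
#' `CL`) with a z coordinate in every frame, sampled on a uniform time grid.
#'
#' @param times_fs Numeric vector of frame times in femtoseconds; strictly
#'   increasing with uniform spacing (relative tolerance 1e-6).
#' @param z Numeric matrix, `length(times_fs)` rows, one column per particle:
#'   pore-axis coordinate in nm.  No missing values are allowed: every
#'   particle must have a coordinate in every frame.
#' @param species Character vector, one of `"K"`, `"W"`, `"O"`, `"CL"` per
#'   particle.
#' @param id Particle identifiers; default taken from `colnames(z)` or
#'   generated as `species + index`.
#' @param x,y Optional matrices of transverse coordinates (nm), same shape
#'   as `z`; needed only by the geometry module.
#' @param box_z Extent of the simulation cell along z in nm.
#' @param metadata Free-form named list (temperature, field parameters,
#'   seed, ...).
#' @return An object of class `trajectory` with elements `times_fs`, `z`,
#'   `x`, `y`, `id`, `species`, `box_z`, `metadata`.
#' @seealso [read_trajectory()], [write_trajectory()], [simulate_channel()]
#' @export
trajectory <- function(times_fs, z, species, id = NULL, x = NULL, y = NULL,
                       box_z, metadata = list()) {
  z <- as.matrix(z)
  times_fs <- as.numeric(times_fs)
  if (length(times_fs) != nrow(z))
    stop("length(times_fs) must equal nrow(z)")
  if (length(times_fs) < 1L) stop("trajectory needs at least one frame")
  if (anyNA(times_fs)) stop("times contain missing values")
  if (length(times_fs) > 1L) {
    dts <- diff(times_fs)
    if (any(dts <= 0)) stop("times must be strictly increasing")
    dt <- dts[1L]
    if (any(abs(dts - dt) > 1e-6 * dt))
      stop("non-uniform time step: frame spacing varies by more than 1 part in 1e6")
  }
  if (anyNA(z))
    stop("coordinate gap: every particle needs a z value in every frame")
  species <- as.character(species)
  if (length(species) != ncol(z))
    stop("one species label per particle required")
  bad <- setdiff(unique(species), SPECIES_ALPHABET)
  if (length(bad))
    stop("unknown species label(s): ", paste(bad, collapse = ", "),
         " (allowed: ", paste(SPECIES_ALPHABET, collapse = ", "), ")")
  if (is.null(id)) id <- colnames(z)
  if (is.null(id)) id <- paste0(species, seq_along(species))
  id <- as.character(id)
  if (anyDuplicated(id)) stop("particle ids must be unique")
  if (length(id) != ncol(z)) stop("one id per particle required")
  colnames(z) <- id
  chk_aux <- function(m, nm) {
    if (is.null(m)) return(NULL)
    m <- as.matrix(m)
    if (!identical(dim(m), dim(z)))
      stop(nm, " must have the same dimensions as z")
    if (anyNA(m)) stop("coordinate gap in ", nm)
    colnames(m) <- id
    m
  }
  x <- chk_aux(x, "x"); y <- chk_aux(y, "y")
  if (!is.numeric(box_z) || length(box_z) != 1L || !is.finite(box_z) || box_z <= 0)
    stop("box_z must be a single positive number (nm)")
  structure(list(times_fs = times_fs, z = z, x = x, y = y, id = id,
                 species = species, box_z = box_z, metadata = metadata),
            class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("<trajectory> %d frames x %d particles, dt = %g fs, box_z = %g nm\n",
              n_frames(x), length(x$id), frame_dt(x), x$box_z))
  cat("  species:", paste(sprintf("%s=%d", names(table(x$species)),
                                  as.integer(table(x$species))), collapse = " "), "\n")
  if (length(x$metadata))
    cat("  metadata:", paste(names(x$metadata), collapse = ", "), "\n")
  invisible(x)
}

#' Number of frames in a trajectory
#' @param traj A [trajectory()].
#' @return Integer frame count.
#' @export
n_frames <- function(traj) length(traj$times_fs)

#' Frame spacing of a trajectory in fs
#' @param traj A [trajectory()].
#' @return Time step between stored frames (fs); `NA` for a 1-frame trajectory.
#' @export
frame_dt <- function(traj) {
  if (n_frames(traj) < 2L) return(NA_real_)
  traj$times_fs[2L] - traj$times_fs[1L]
}

#' Total duration of a trajectory in ns
#' @param traj A [trajectory()].
#' @return `max(times) - min(times)` in nanoseconds.
#' @export
duration_ns <- function(traj) {
  (traj$times_fs[n_frames(traj)] - traj$times_fs[1L]) * 1e-6
}

#' Drop frames before a discard (equilibration) time
#' @param traj A [trajectory()].
#' @param discard_time_ns Frames with `t < discard_time_ns` are dropped.
#' @return A [trajectory()] restricted to the retained frames.
#' @export
discard_frames <- function(traj, discard_time_ns) {
  keep <- traj$times_fs >= discard_time_ns * 1e6
  if (!any(keep)) stop("discard_time removes every frame")
  trajectory(traj$times_fs[keep], traj$z[keep, , drop = FALSE], traj$species,
             id = traj$id,
             x = if (!is.null(traj$x)) traj$x[keep, , drop = FALSE],
             y = if (!is.null(traj$y)) traj$y[keep, , drop = FALSE],
             box_z = traj$box_z, metadata = traj$metadata)
}
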