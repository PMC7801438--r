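#' Particle trajectory container
#'
#' Frames x particles x 3 coordinate record with uniform frame times and an
#' optional orthorhombic box. Coordinates are in Angstrom, times in ps.
#'
#' @param positions Numeric array `[n_frames, n_particles, 3]`, or a
#'   `n_frames x 3` matrix for a single particle.
#' @param times Frame times in ps, strictly increasing with uniform spacing
#'   (relative tolerance 1e-6).
#' @param box Orthorhombic box edge lengths in Angstrom (length 3, or a scalar
#'   recycled), or `NULL` when no box applies.
#' @param particle_ids Stable particle identifiers; default `"p1", "p2", ...`.
#' @param wrapped Logical: are coordinates wrapped into the box?
#' @return A `trajectory` object.
#' @export
trajectory <- function(positions, times, box = NULL, particle_ids = NULL,
                       wrapped = FALSE) {
  if (is.matrix(positions) && ncol(positions) == 3)
    positions <- array(positions, dim = c(nrow(positions), 1L, 3L))
  if (!is.array(positions) || length(dim(positions)) != 3 || dim(positions)[3] != 3)
    stop_domain("positions must be an [n_frames, n_particles, 3] array")
  n_frames <- dim(positions)[1]
  n_particles <- dim(positions)[2]
  times <- as.numeric(times)
  if (length(times) != n_frames)
    stop_domain("times (%d) must match the number of frames (%d)",
                length(times), n_frames)
  if (n_frames >= 2) {
    dts <- diff(times)
    if (any(dts <= 0))
      stop_domain("frame times must be strictly increasing")
    dt <- dts[1]
    if (any(abs(dts - dt) > 1e-6 * dt))
      stop_domain("frame times must be uniformly spaced (relative tolerance 1e-6); non-uniform input is not resampled")
  } else {
    dt <- NA_real_
  }
  if (!is.null(box)) {
    box <- as.numeric(box)
    if (length(box) == 1) box <- rep(box, 3)
    if (length(box) != 3 || any(!is.finite(box)) || any(box <= 0))
      stop_domain("box must be 3 positive edge lengths (Angstrom)")
  }
  if (is.null(particle_ids)) particle_ids <- paste0("p", seq_len(n_particles))
  if (length(particle_ids) != n_particles)
    stop_domain("particle_ids (%d) must match the number of particles (%d)",
                length(particle_ids), n_particles)
  if (anyDuplicated(particle_ids))
    stop_domain("particle_ids must be unique")
  structure(list(positions = positions, times = times, dt = dt, box = box,
                 particle_ids = as.character(particle_ids),
                 wrapped = isTRUE(wrapped)),
            class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  d <- dim(x$positions)
  cat(sprintf("<trajectory> %d frames x %d particles, dt = %s ps, %s%s\n",
              d[1], d[2], format(x$dt),
              if (is.null(x$box)) "no box"
              else sprintf("box %.4g x %.4g x %.4g A", x$box[1], x$box[2], x$box[3]),
              if (x$wrapped) ", wrapped" else ""))
  invisible(x)
}

n_frames <- function(traj) dim(traj$positions)[1]
n_particles <- function(traj) dim(traj$positions)[2]

#' Unwrap periodic-boundary coordinates
#'
#' Reconstructs continuous particle paths from box-wrapped coordinates by the
#' minimum-image convention: every frame-to-frame displacement component is
#' mapped into `(-L/2, +L/2]` before re-accumulation. The first frame is
#' unchanged. A true physical jump beyond L/2 per frame is indistinguishable
#' from a wrap and is folded back — the convention is the definition.
#'
#' @param traj A wrapped [trajectory()] with a box.
#' @return The trajectory with continuous coordinates and `wrapped = FALSE`.
#' @export
unwrap_pbc <- function(traj) {
  stopifnot(inherits(traj, "trajectory"))
  if (is.null(traj$box))
    stop_config("unwrap_pbc needs a box; trajectory has none")
  if (!traj$wrapped)
    stop_config("trajectory is not flagged as wrapped")
  pos <- traj$positions
  nf <- dim(pos)[1]
  if (nf >= 2) {
    for (k in 1:3) {
      L <- traj$box[k]
      xk <- pos[, , k, drop = FALSE]
      dim(xk) <- dim(pos)[1:2]
      d <- diff(xk)
      ## map each displacement component into (-L/2, +L/2]
      d <- d - L * ceiling(d / L - 0.5)
      xk <- rbind(xk[1, , drop = FALSE], d)
      xk <- apply(xk, 2, cumsum)
      pos[, , k] <- xk
    }
  }
  trajectory(pos, traj$times, traj$box, traj$particle_ids, wrapped = FALSE)
}

#' Wrap coordinates into the periodic box
#'
#' Maps every coordinate into `[0, L)` per axis. Inverse of [unwrap_pbc()] up
#' to the box period.
#'
#' @param traj A [trajectory()] with a box.
#' @return The trajectory with wrapped coordinates and `wrapped = TRUE`.
#' @export
wrap_pbc <- function(traj) {
  stopifnot(inherits(traj, "trajectory"))
  if (is.null(traj$box))
    stop_config("wrap_pbc needs a box; trajectory has none")
  pos <- traj$positions
  for (k in 1:3) pos[, , k] <- pos[, , k] %% traj$box[k]
  trajectory(pos, traj$times, traj$box, traj$particle_ids, wrapped = TRUE)
}

## resolve a selection (ids, logical, or integer indices) to integer indices
resolve_selection <- function(traj, selection) {
  if (is.null(selection)) return(seq_len(n_particles(traj)))
  if (is.logical(selection)) {
    if (length(selection) != n_particles(traj))
      stop_domain("logical selection length must equal particle count")
    sel <- which(selection)
  } else if (is.character(selection)) {
    sel <- match(selection, traj$particle_ids)
    if (anyNA(sel))
      stop_domain("unknown particle id(s): %s",
                  paste(selection[is.na(sel)], collapse = ", "))
  } else {
    sel <- as.integer(selection)
    if (any(sel < 1 | sel > n_particles(traj)))
      stop_domain("particle index out of range")
  }
  if (length(sel) == 0) stop_domain("empty particle selection")
  sel
}
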