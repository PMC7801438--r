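## Channel geometry, hydropathy and water-count statistics. A channel is an
## ordered centerline polyline with optional per-point radii and a list of
## lining residues; water counting measures the minimum distance from each
## water to the polyline (point-to-segment, not point-to-vertex).

#' Channel centerline description
#'
#' @param points Ordered centerline coordinates, an `n x 3` matrix (Angstrom),
#'   n >= 1; consecutive points must be distinct.
#' @param radii Optional local channel radius per point (Angstrom, > 0).
#' @param lining_residues Optional channel-lining residues: a data.frame with
#'   columns `name` (3-letter code) and `number`, or a list of
#'   `list("ILE", 127)` pairs.
#' @param label Channel class tag: `"interface"`, `"porous"`, `"transient"`
#'   or `"other"`.
#' @return A `channel_path` object.
#' @export
channel_path <- function(points, radii = NULL, lining_residues = NULL,
                         label = c("other", "interface", "porous", "transient")) {
  label <- match.arg(label)
  points <- as.matrix(points)
  if (ncol(points) != 3 || nrow(points) < 1)
    stop_domain("points must be an n x 3 matrix with n >= 1")
  storage.mode(points) <- "double"
  if (nrow(points) >= 2) {
    seg <- sqrt(rowSums((points[-1, , drop = FALSE] -
                           points[-nrow(points), , drop = FALSE])^2))
    if (any(seg == 0)) stop_domain("consecutive centerline points must be distinct")
  }
  if (!is.null(radii)) {
    radii <- as.numeric(radii)
    if (length(radii) != nrow(points))
      stop_domain("radii (%d) must match the number of points (%d)",
                  length(radii), nrow(points))
    if (any(!is.finite(radii)) || any(radii <= 0))
      stop_domain("radii must be finite and positive")
  }
  if (!is.null(lining_residues)) {
    if (is.list(lining_residues) && !is.data.frame(lining_residues))
      lining_residues <- data.frame(
        name = vapply(lining_residues, function(p) as.character(p[[1]]), ""),
        number = vapply(lining_residues, function(p) as.integer(p[[2]]), 1L))
    if (!all(c("name", "number") %in% names(lining_residues)))
      stop_domain("lining_residues needs columns 'name' and 'number'")
    lining_residues$name <- toupper(as.character(lining_residues$name))
  }
  structure(list(points = points, radii = radii,
                 lining_residues = lining_residues, label = label),
            class = "channel_path")
}

#' @export
print.channel_path <- function(x, ...) {
  cat(sprintf("<channel_path> '%s': %d points, length %.4g A%s%s\n",
              x$label, nrow(x$points), channel_length(x),
              if (!is.null(x$radii)) sprintf(", bottleneck %.3g A", min(x$radii)) else "",
              if (!is.null(x$lining_residues))
                sprintf(", %d lining residues", nrow(x$lining_residues)) else ""))
  invisible(x)
}

#' Channel arc length
#'
#' Polyline arc length: sum of consecutive point distances (0 for a single
#' point).
#'
#' @param path A [channel_path()].
#' @return Length in Angstrom.
#' @export
channel_length <- function(path) {
  stopifnot(inherits(path, "channel_path"))
  p <- path$points
  if (nrow(p) < 2) return(0)
  sum(sqrt(rowSums((p[-1, , drop = FALSE] - p[-nrow(p), , drop = FALSE])^2)))
}

#' Channel bottleneck
#'
#' The minimum local radius along the centerline and its first index (ties
#' break to the first occurrence). The conventional reported channel "width"
#' is the diameter, `2 * radius`.
#'
#' @param path A [channel_path()] with radii.
#' @return List with `radius` (Angstrom), `index`, `width` (= 2 radius).
#' @export
channel_bottleneck <- function(path) {
  stopifnot(inherits(path, "channel_path"))
  if (is.null(path$radii))
    stop_config("channel has no radii; bottleneck undefined")
  i <- which.min(path$radii)          # first occurrence on ties
  list(radius = path$radii[i], index = i, width = 2 * path$radii[i])
}

#' Kyte-Doolittle hydropathy scale
#'
#' The standard per-residue hydropathy values (positive = hydrophobic),
#' named by 3-letter amino-acid code.
#'
#' @return Named numeric vector of length 20.
#' @export
kyte_doolittle <- function() {
  c(ILE = 4.5, VAL = 4.2, LEU = 3.8, PHE = 2.8, CYS = 2.5, MET = 1.9,
    ALA = 1.8, GLY = -0.4, THR = -0.7, SER = -0.8, TRP = -0.9, TYR = -1.3,
    PRO = -1.6, HIS = -3.2, GLU = -3.5, GLN = -3.5, ASP = -3.5, ASN = -3.5,
    LYS = -3.9, ARG = -4.5)
}

#' Per-segment hydropathy profile of the channel lining
#'
#' Splits the lining residues into `n_segments` consecutive groups (by residue
#' order along the channel, since the lining list carries no coordinates) and
#' averages the normalized Kyte-Doolittle hydropathy (raw value / 4.5, so the
#' scale is `[-1, 1]` with +1 fully hydrophobic) within each segment.
#'
#' @param path A [channel_path()] with `lining_residues`.
#' @param n_segments Number of segments, >= 1.
#' @return List with `segments` (data.frame: `segment`, `n_residues`,
#'   `mean_hydropathy`), `min`, `max` (overall per-residue extremes).
#' @export
hydropathy_profile <- function(path, n_segments = 10) {
  stopifnot(inherits(path, "channel_path"))
  if (is.null(path$lining_residues) || nrow(path$lining_residues) == 0)
    stop_config("channel has no lining residues")
  if (n_segments < 1) stop_domain("n_segments must be >= 1")
  kd <- kyte_doolittle()
  res <- path$lining_residues$name
  unknown <- setdiff(unique(res), names(kd))
  if (length(unknown) > 0)
    stop_domain("unknown residue name(s): %s", paste(unknown, collapse = ", "))
  h <- unname(kd[res]) / 4.5
  m <- length(h)
  n_segments <- min(n_segments, m)
  seg_of <- ceiling(seq_along(h) * n_segments / m)
  means <- tapply(h, seg_of, mean)
  list(segments = data.frame(segment = as.integer(names(means)),
                             n_residues = as.integer(table(seg_of)),
                             mean_hydropathy = as.numeric(means)),
       min = min(h), max = max(h))
}

## minimum distance from each row of `pts` (n x 3) to the polyline `line`
## (m x 3): point-to-segment distances, minimized over segments
min_dist_to_polyline <- function(pts, line) {
  pts <- as.matrix(pts); line <- as.matrix(line)
  if (nrow(line) == 1) {
    return(sqrt(rowSums(sweep(pts, 2, line[1, ])^2)))
  }
  A <- line[-nrow(line), , drop = FALSE]
  E <- line[-1, , drop = FALSE] - A
  len2 <- rowSums(E^2)
  best <- rep(Inf, nrow(pts))
  for (j in seq_len(nrow(A))) {
    W <- sweep(pts, 2, A[j, ])
    tt <- pmin(pmax(as.vector(W %*% E[j, ]) / len2[j], 0), 1)
    d2 <- rowSums((W - outer(tt, E[j, ]))^2)
    best <- pmin(best, d2)
  }
  sqrt(best)
}

#' Per-frame water counts around a channel
#'
#' Counts, in every frame, the selected particles whose minimum distance to
#' the channel centerline polyline is at most `cutoff` (the boundary counts
#' as inside). The caller selects which particles are water oxygens; no
#' chemistry is inferred.
#'
#' @param traj A [trajectory()].
#' @param path A [channel_path()].
#' @param cutoff Distance cutoff in Angstrom (> 0); default 3.
#' @param water_selection Particle ids/indices/logical; `NULL` = all.
#' @return A `water_count_series`: list with `frame_times` (ps), `counts`,
#'   `cutoff`.
#' @export
count_channel_waters <- function(traj, path, cutoff = 3.0,
                                 water_selection = NULL) {
  stopifnot(inherits(traj, "trajectory"), inherits(path, "channel_path"))
  if (!is.finite(cutoff) || cutoff <= 0) stop_domain("cutoff must be > 0")
  sel <- resolve_selection(traj, water_selection)
  counts <- integer(n_frames(traj))
  for (f in seq_len(n_frames(traj))) {
    pts <- traj$positions[f, sel, , drop = FALSE]
    dim(pts) <- c(length(sel), 3L)
    counts[f] <- sum(min_dist_to_polyline(pts, path$points) <= cutoff)
  }
  structure(list(frame_times = traj$times, counts = counts, cutoff = cutoff),
            class = "water_count_series")
}

#' @export
print.water_count_series <- function(x, ...) {
  cat(sprintf("<water_count_series> %d frames, counts %d-%d (cutoff %.3g A)\n",
              length(x$counts), min(x$counts), max(x$counts), x$cutoff))
  invisible(x)
}

#' Mean and standard deviation of channel water counts
#'
#' Mean and sample standard deviation (n - 1 denominator) of the counts over
#' strided frames. The default stride aims at ~10 frames spaced 100 ps apart
#' when the trajectory is long enough (stride = round(100 ps / frame
#' interval), floored at 1).
#'
#' @param series A `water_count_series` from [count_channel_waters()].
#' @param frame_stride Stride over frames, >= 1; `NULL` = default above.
#' @return List with `mean`, `sd` (`NA` when fewer than 2 strided frames),
#'   `n_frames_used`, `stride`.
#' @export
water_count_stats <- function(series, frame_stride = NULL) {
  stopifnot(inherits(series, "water_count_series"))
  n <- length(series$counts)
  if (n == 0) stop_insufficient_data("empty water-count series")
  if (is.null(frame_stride)) {
    dt <- if (n >= 2) series$frame_times[2] - series$frame_times[1] else NA_real_
    frame_stride <- if (is.finite(dt) && dt > 0) max(1L, round(100 / dt)) else 1L
  }
  if (frame_stride < 1) stop_domain("frame_stride must be >= 1")
  idx <- seq(1L, n, by = as.integer(frame_stride))
  x <- series$counts[idx]
  list(mean = mean(x),
       sd = if (length(x) >= 2) stats::sd(x) else NA_real_,
       n_frames_used = length(x), stride = as.integer(frame_stride))
}
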