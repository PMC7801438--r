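## File formats: extended XYZ (canonical trajectory exchange format),
## minimal multi-MODEL PDB (read-only, via bio3d), 2-column rate CSV,
## channel-path JSON/CSV, MSD CSV and JSON fit reports. Units are embedded
## in column/key names so J vs kJ ambiguities cannot recur in files.

#' Write a trajectory as extended XYZ
#'
#' One block per frame: particle count, then a comment line
#' `time_ps=<t> box=<Lx>,<Ly>,<Lz>` (box omitted when absent), then one
#' `<id> <x> <y> <z>` line per particle (6 decimals).
#'
#' @param traj A [trajectory()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_xyz_trajectory <- function(traj, path) {
  stopifnot(inherits(traj, "trajectory"))
  np <- n_particles(traj)
  con <- file(path, "w")
  on.exit(close(con))
  for (f in seq_len(n_frames(traj))) {
    comment <- sprintf("time_ps=%.6f", traj$times[f])
    if (!is.null(traj$box))
      comment <- paste0(comment, sprintf(" box=%.6f,%.6f,%.6f",
                                         traj$box[1], traj$box[2], traj$box[3]))
    writeLines(c(as.character(np), comment), con)
    xyz <- traj$positions[f, , , drop = FALSE]
    dim(xyz) <- c(np, 3L)
    writeLines(sprintf("%s %.6f %.6f %.6f", traj$particle_ids,
                       xyz[, 1], xyz[, 2], xyz[, 3]), con)
  }
  invisible(path)
}

#' Read an extended-XYZ trajectory
#'
#' Parses the format written by [write_xyz_trajectory()]. Frame times come
#' from the `time_ps=` comment field; if absent they are synthesized as
#' `0, dt, 2 dt, ...` from the `dt` argument. The box is taken from the first
#' frame's `box=` field.
#'
#' @param path Input file.
#' @param dt Frame interval used when the file carries no times (ps).
#' @param wrapped Are the stored coordinates box-wrapped?
#' @return A [trajectory()].
#' @export
read_xyz_trajectory <- function(path, dt = 1, wrapped = FALSE) {
  if (!file.exists(path)) stop_format("file not found: %s", path)
  lines <- readLines(path)
  i <- 1L; frames <- list(); times <- numeric(); box <- NULL
  ids <- NULL; frame_no <- 0L
  while (i <= length(lines)) {
    if (!nzchar(trimws(lines[i]))) { i <- i + 1L; next }
    np <- suppressWarnings(as.integer(trimws(lines[i])))
    if (is.na(np) || np < 1)
      stop_format("expected a particle count on line %d", i)
    frame_no <- frame_no + 1L
    if (i + 1L + np > length(lines))
      stop_format("truncated frame %d (line %d)", frame_no, i)
    comment <- lines[i + 1L]
    tm <- regmatches(comment, regexec("time_ps=([-0-9.eE+]+)", comment))[[1]]
    times <- c(times, if (length(tm) == 2) as.numeric(tm[2]) else NA_real_)
    bm <- regmatches(comment, regexec("box=([-0-9.eE+]+),([-0-9.eE+]+),([-0-9.eE+]+)",
                                      comment))[[1]]
    if (length(bm) == 4 && is.null(box)) box <- as.numeric(bm[2:4])
    rows <- strsplit(trimws(lines[i + 1L + seq_len(np)]), "[[:space:]]+")
    if (any(lengths(rows) < 4))
      stop_format("malformed atom line in frame %d", frame_no)
    fid <- vapply(rows, `[`, "", 1)
    xyz <- matrix(as.numeric(unlist(lapply(rows, `[`, 2:4))), ncol = 3,
                  byrow = TRUE)
    if (anyNA(xyz)) stop_format("non-numeric coordinate in frame %d", frame_no)
    if (is.null(ids)) {
      ids <- fid
    } else if (length(fid) != length(ids)) {
      stop_format("frame %d has %d particles; frame 1 has %d",
                  frame_no, length(fid), length(ids))
    }
    frames[[frame_no]] <- xyz
    i <- i + 2L + np
  }
  if (frame_no == 0) stop_format("no frames found in %s", path)
  if (anyNA(times)) times <- (seq_len(frame_no) - 1) * dt
  pos <- array(0, dim = c(frame_no, length(ids), 3))
  for (f in seq_len(frame_no)) pos[f, , ] <- frames[[f]]
  trajectory(pos, times, box = box, particle_ids = make.unique(ids),
             wrapped = wrapped)
}

#' Read a minimal multi-MODEL PDB trajectory
#'
#' Reads coordinates from MODEL/ENDMDL blocks (via bio3d) and the box from
#' the CRYST1 record; only coordinates, atom names and residue numbers are
#' used. MODEL/ENDMDL pairing and per-model atom counts are validated with
#' the offending model number reported.
#'
#' @param path Input PDB file.
#' @param dt Frame interval in ps used to synthesize times `0, dt, 2 dt, ...`.
#' @param wrapped Are the stored coordinates box-wrapped?
#' @return A [trajectory()].
#' @export
read_pdb_trajectory <- function(path, dt = 1, wrapped = FALSE) {
  if (!file.exists(path)) stop_format("file not found: %s", path)
  lines <- readLines(path)
  rec <- substr(lines, 1, 6)
  model_ln <- which(rec == "MODEL ")
  endmdl_ln <- which(rec == "ENDMDL")
  if (length(model_ln) != length(endmdl_ln)) {
    n <- max(length(model_ln), length(endmdl_ln))
    stop_format("MODEL/ENDMDL pairs mismatched at model %d (%d MODEL vs %d ENDMDL)",
                n, length(model_ln), length(endmdl_ln))
  }
  if (length(model_ln) > 0 && any(endmdl_ln < model_ln))
    stop_format("ENDMDL before MODEL at model %d",
                which(endmdl_ln < model_ln)[1])
  n_atoms <- if (length(model_ln) > 0) {
    mapply(function(a, b) sum(rec[a:b] %in% c("ATOM  ", "HETATM")),
           model_ln, endmdl_ln)
  } else {
    sum(rec %in% c("ATOM  ", "HETATM"))
  }
  if (length(unique(n_atoms)) > 1)
    stop_format("model %d has %d atoms; model 1 has %d",
                which(n_atoms != n_atoms[1])[1], n_atoms[which(n_atoms != n_atoms[1])[1]],
                n_atoms[1])
  box <- NULL
  cr <- lines[rec == "CRYST1"]
  if (length(cr) >= 1) {
    box <- as.numeric(c(substr(cr[1], 7, 15), substr(cr[1], 16, 24),
                        substr(cr[1], 25, 33)))
    if (anyNA(box)) stop_format("unparseable CRYST1 record")
  }
  pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
  xyz <- pdb$xyz
  nf <- nrow(xyz); np <- ncol(xyz) / 3
  pos <- array(0, dim = c(nf, np, 3))
  for (k in 1:3) pos[, , k] <- xyz[, seq(k, ncol(xyz), by = 3), drop = FALSE]
  ids <- make.unique(paste0(trimws(pdb$atom$elety), pdb$atom$resno))
  trajectory(pos, times = (seq_len(nf) - 1) * dt, box = box,
             particle_ids = ids, wrapped = wrapped)
}

#' Read a temperature-indexed rate table
#'
#' CSV with header `temperature_K,value`; lines starting with `#` are
#' comments. Temperatures are canonicalized ascending; exact duplicates and
#' non-numeric cells are errors reported with their line number.
#'
#' @param path Input CSV file.
#' @param value_kind,label Passed to [rate_series()].
#' @return A [rate_series()].
#' @export
read_rate_csv <- function(path, value_kind = "rate", label = "") {
  if (!file.exists(path)) stop_format("file not found: %s", path)
  lines <- readLines(path)
  keep <- which(nzchar(trimws(lines)) & !startsWith(trimws(lines), "#"))
  if (length(keep) < 1) stop_format("empty rate table: %s", path)
  header <- strsplit(trimws(lines[keep[1]]), ",")[[1]]
  if (length(header) < 2 || trimws(header[1]) != "temperature_K" ||
      trimws(header[2]) != "value")
    stop_format("expected header 'temperature_K,value' on line %d", keep[1])
  rows <- keep[-1]
  if (length(rows) == 0) stop_format("no data rows in %s", path)
  temps <- vals <- numeric(length(rows))
  for (j in seq_along(rows)) {
    cells <- strsplit(trimws(lines[rows[j]]), ",")[[1]]
    if (length(cells) < 2)
      stop_format("line %d: expected 2 comma-separated cells", rows[j])
    tv <- suppressWarnings(as.numeric(cells[1:2]))
    if (anyNA(tv))
      stop_format("line %d: non-numeric cell '%s'", rows[j],
                  cells[1:2][is.na(tv)][1])
    temps[j] <- tv[1]; vals[j] <- tv[2]
  }
  rate_series(temps, vals, value_kind = value_kind, label = label)
}

#' Write a rate series as CSV
#'
#' @param series A [rate_series()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_rate_csv <- function(series, path) {
  stopifnot(inherits(series, "rate_series"))
  writeLines(c("temperature_K,value",
               sprintf("%.10g,%.10g", series$temperatures, series$values)),
             path)
  invisible(path)
}

#' Write an MSD curve as CSV
#'
#' Columns `lag_ps,msd_A2,n_samples`.
#'
#' @param curve An [msd_curve()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_msd_csv <- function(curve, path) {
  stopifnot(inherits(curve, "msd_curve"))
  writeLines(c("lag_ps,msd_A2,n_samples",
               sprintf("%.10g,%.10g,%g", curve$lags, curve$msd,
                       curve$n_samples)),
             path)
  invisible(path)
}

#' Read a channel path from JSON
#'
#' Schema: `{"label": ..., "points": [[x,y,z], ...], "radii": [...],
#' "lining_residues": [["ILE", 127], ...]}` (radii and lining optional).
#'
#' @param path Input JSON file.
#' @return A [channel_path()].
#' @export
read_channel_json <- function(path) {
  if (!file.exists(path)) stop_format("file not found: %s", path)
  obj <- jsonlite::fromJSON(path, simplifyMatrix = TRUE)
  if (is.null(obj$points)) stop_format("channel JSON lacks 'points'")
  lining <- NULL
  if (!is.null(obj$lining_residues) && length(obj$lining_residues) > 0) {
    lr <- obj$lining_residues
    if (is.matrix(lr) || is.data.frame(lr)) {
      lining <- data.frame(name = as.character(lr[, 1]),
                           number = as.integer(lr[, 2]))
    } else {
      lining <- data.frame(name = vapply(lr, function(p) as.character(p[[1]]), ""),
                           number = vapply(lr, function(p) as.integer(p[[2]]), 1L))
    }
  }
  label <- if (is.null(obj$label)) "other" else obj$label
  channel_path(obj$points, radii = obj$radii, lining_residues = lining,
               label = label)
}

#' Write a channel path as JSON
#'
#' @param path_obj A [channel_path()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_channel_json <- function(path_obj, path) {
  stopifnot(inherits(path_obj, "channel_path"))
  obj <- list(label = path_obj$label,
              points = unname(path_obj$points))
  if (!is.null(path_obj$radii)) obj$radii <- path_obj$radii
  if (!is.null(path_obj$lining_residues))
    obj$lining_residues <- unname(Map(function(n, r) list(n, r),
                                      path_obj$lining_residues$name,
                                      path_obj$lining_residues$number))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a channel path from CSV (`x,y,z,radius`)
#'
#' @param path Input CSV file.
#' @param label Channel class tag.
#' @return A [channel_path()].
#' @export
read_channel_csv <- function(path, label = "other") {
  if (!file.exists(path)) stop_format("file not found: %s", path)
  df <- utils::read.csv(path, comment.char = "#")
  if (!all(c("x", "y", "z") %in% names(df)))
    stop_format("channel CSV needs columns x,y,z[,radius]")
  channel_path(as.matrix(df[, c("x", "y", "z")]),
               radii = if ("radius" %in% names(df)) df$radius else NULL,
               label = label)
}

#' Write a water-count series as CSV (`time_ps,count`)
#'
#' @param series A `water_count_series`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_water_counts_csv <- function(series, path) {
  stopifnot(inherits(series, "water_count_series"))
  writeLines(c("time_ps,count",
               sprintf("%.10g,%d", series$frame_times, series$counts)), path)
  invisible(path)
}

#' Write a kinetics fit report as JSON
#'
#' Emits the fitted parameters with unit-tagged keys (`ln_pre`,
#' `B_J_per_mol`, `C_J2_per_mol2`, `r_squared`), the activation energy in
#' kJ mol^-1 at the requested temperatures, the model classification, and a
#' provenance block (package version, seed, settings, inputs).
#'
#' @param fit A `super_arrhenius_fit`.
#' @param path Output JSON file.
#' @param ea_temperatures Temperatures (K) at which to report Ea.
#' @param seed,inputs,settings Optional provenance entries.
#' @return `path`, invisibly.
#' @export
write_fit_report <- function(fit, path, ea_temperatures = c(290, 300, 310),
                             seed = NULL, inputs = NULL, settings = NULL) {
  stopifnot(inherits(fit, "super_arrhenius_fit"))
  ea <- activation_energy(fit, ea_temperatures) / 1000
  names(ea) <- sprintf("%g", ea_temperatures)
  report <- list(
    model = "ln v = ln_pre + B/(R T) + C/(R T)^2, R = 8.314 J K^-1 mol^-1",
    value_kind = fit$value_kind,
    ln_pre = fit$ln_pre,
    B_J_per_mol = fit$B,
    C_J2_per_mol2 = fit$C,
    r_squared = fit$r_squared,
    classification = classify_arrhenius(fit),
    Ea_kJ_per_mol = as.list(ea),
    provenance = list(package = "hydrokin",
                      version = as.character(utils::packageVersion("hydrokin")),
                      seed = seed, inputs = inputs, settings = settings)
  )
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' Read a kinetics fit report back into a fit object
#'
#' @param path JSON file written by [write_fit_report()].
#' @return A `super_arrhenius_fit` (parameters only; covariance zero).
#' @export
read_fit_report <- function(path) {
  if (!file.exists(path)) stop_format("file not found: %s", path)
  obj <- jsonlite::fromJSON(path)
  for (k in c("ln_pre", "B_J_per_mol", "C_J2_per_mol2"))
    if (is.null(obj[[k]])) stop_format("fit report lacks '%s'", k)
  super_arrhenius_params(obj$ln_pre, obj$B_J_per_mol, obj$C_J2_per_mol2,
                         value_kind = if (is.null(obj$value_kind)) "rate"
                                      else obj$value_kind)
}
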