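## End-to-end pipeline: simulate a temperature sweep of channel trajectories,
## estimate D(T) by MSD, fit Arrhenius vs super-Arrhenius, write reports.
## Configuration is validated in full before any computation starts, so a
## bad setting can never surface as a module error halfway through a run.

#' Build and validate a pipeline configuration
#'
#' Collects every tunable of the trajectory -> MSD -> D(T) -> deformed-
#' Arrhenius pipeline and validates the whole set against the downstream
#' preconditions (temperature count, hop-probability validity, window shape,
#' ...) before anything runs.
#'
#' @param temperatures Sweep temperatures in K, >= 2 distinct values.
#' @param n_particles,n_frames,dt,site_spacing,barrier,attempt_rate,radial_sigma,occupancy_decay,bulk_D
#'   Passed to [simulate_channel_hopping()].
#' @param msd_max_lag,msd_origins Passed to [compute_msd()].
#' @param fit_model,n_dim,fit_window,fit_drift Passed to [fit_msd()].
#' @param ea_temperatures Temperatures (K) at which reports state Ea.
#' @param output_dir Directory for CSV/JSON artifacts (`NULL` = do not write).
#' @param seed Integer master seed; per-temperature simulation seeds are
#'   derived from it.
#' @param log_level `"info"` (progress on stderr) or `"quiet"`.
#' @return A validated `pipeline_config` list.
#' @export
pipeline_config <- function(temperatures = seq(270, 340, by = 10),
                            n_particles = 120, n_frames = 400, dt = 1,
                            site_spacing = 3, barrier = 25000,
                            attempt_rate = 2000, radial_sigma = 0.5,
                            occupancy_decay = 1, bulk_D = 0.2,
                            msd_max_lag = NULL, msd_origins = "all",
                            fit_model = "dim_2nDt", n_dim = 3,
                            fit_window = NULL, fit_drift = FALSE,
                            ea_temperatures = c(290, 300, 310),
                            output_dir = NULL, seed = 1,
                            log_level = c("info", "quiet")) {
  log_level <- match.arg(log_level)
  cfg <- list(temperatures = as.numeric(temperatures),
              n_particles = n_particles, n_frames = n_frames, dt = dt,
              site_spacing = site_spacing, barrier = barrier,
              attempt_rate = attempt_rate, radial_sigma = radial_sigma,
              occupancy_decay = occupancy_decay, bulk_D = bulk_D,
              msd_max_lag = msd_max_lag, msd_origins = msd_origins,
              fit_model = fit_model, n_dim = n_dim,
              fit_window = fit_window, fit_drift = fit_drift,
              ea_temperatures = ea_temperatures,
              output_dir = output_dir, seed = as.integer(seed),
              log_level = log_level)
  validate_pipeline_config(cfg)
  structure(cfg, class = "pipeline_config")
}

#' Validate a pipeline configuration
#'
#' Checks every downstream precondition up front; throws a
#' `hydrokin_config_error` describing the first violation.
#'
#' @param cfg A configuration list as built by [pipeline_config()].
#' @return `cfg`, invisibly, when valid.
#' @export
validate_pipeline_config <- function(cfg) {
  fail <- function(msg, ...) stop_config(paste0("config: ", msg), ...)
  tt <- cfg$temperatures
  if (length(tt) < 2) fail("need >= 2 temperatures, got %d", length(tt))
  if (any(!is.finite(tt)) || any(tt <= 0)) fail("temperatures must be > 0 K")
  if (anyDuplicated(tt)) fail("duplicate temperatures in the sweep")
  for (f in c("n_particles", "n_frames")) {
    v <- cfg[[f]]
    if (!is.numeric(v) || length(v) != 1 || !is.finite(v) || v < 1)
      fail("%s must be a count >= 1", f)
  }
  for (f in c("dt", "site_spacing", "attempt_rate", "bulk_D")) {
    v <- cfg[[f]]
    if (!is.numeric(v) || length(v) != 1 || !is.finite(v) || v <= 0)
      fail("%s must be > 0", f)
  }
  for (f in c("barrier", "radial_sigma", "occupancy_decay")) {
    v <- cfg[[f]]
    if (!is.numeric(v) || length(v) != 1 || !is.finite(v) || v < 0)
      fail("%s must be >= 0", f)
  }
  p_max <- cfg$attempt_rate * cfg$dt *
    exp(-cfg$barrier / (GAS_CONSTANT * max(tt)))
  if (p_max > 0.5)
    fail("hop probability %.3g > 0.5 at T = %g K: reduce dt or attempt_rate",
         p_max, max(tt))
  dur <- (cfg$n_frames - 1) * cfg$dt
  if (!is.null(cfg$msd_max_lag)) {
    if (cfg$msd_max_lag <= 0 || cfg$msd_max_lag > dur)
      fail("msd_max_lag must lie in (0, %g] ps", dur)
  }
  if (!cfg$msd_origins %in% c("all", "single")) fail("msd_origins must be 'all' or 'single'")
  if (!cfg$fit_model %in% c("paper_4Dt", "dim_2nDt")) fail("unknown fit_model '%s'", cfg$fit_model)
  if (cfg$n_dim < 1) fail("n_dim must be >= 1")
  if (!is.null(cfg$fit_window)) {
    fw <- cfg$fit_window
    if (length(fw) != 2 || fw[1] >= fw[2] || fw[1] < 0)
      fail("fit_window must be c(lag_min, lag_max) with 0 <= lag_min < lag_max")
  }
  if (any(cfg$ea_temperatures <= 0)) fail("ea_temperatures must be > 0 K")
  if (length(cfg$seed) != 1 || is.na(cfg$seed)) fail("seed must be one integer")
  invisible(cfg)
}

#' Run the simulate -> MSD -> D(T) -> super-Arrhenius pipeline
#'
#' For each sweep temperature, simulates a channel-hopping trajectory,
#' estimates D by multi-origin MSD, assembles the D(T) series, compares the
#' Arrhenius and deformed-Arrhenius models, and (when `output_dir` is set)
#' writes `diffusion_vs_temperature.csv`, per-temperature MSD curves and
#' `fit_report.json`. Identical config and seed give byte-identical outputs;
#' progress goes to stderr only.
#'
#' @param cfg A [pipeline_config()].
#' @return List: `series` ([rate_series()]), `comparison`
#'   ([compare_models()] result), `fit` (the super-Arrhenius fit),
#'   `classification`, `ea_kJ_per_mol` (at `cfg$ea_temperatures`).
#' @export
run_pipeline <- function(cfg) {
  if (!inherits(cfg, "pipeline_config")) cfg <- do.call(pipeline_config, cfg)
  validate_pipeline_config(cfg)
  say <- function(...) if (cfg$log_level == "info") message(sprintf(...))
  runs <- lapply(seq_along(cfg$temperatures), function(i) {
    Tk <- cfg$temperatures[i]
    say("simulating T = %g K (%d/%d)", Tk, i, length(cfg$temperatures))
    traj <- simulate_channel_hopping(
      n_particles = cfg$n_particles, n_frames = cfg$n_frames, dt = cfg$dt,
      site_spacing = cfg$site_spacing, barrier = cfg$barrier,
      attempt_rate = cfg$attempt_rate, radial_sigma = cfg$radial_sigma,
      occupancy_decay = cfg$occupancy_decay, bulk_D = cfg$bulk_D,
      temperature = Tk, seed = cfg$seed * 1000L + i)
    list(temperature = Tk, trajectory = traj)
  })
  say("estimating D(T) from MSD")
  series <- diffusion_vs_temperature(
    runs, max_lag = cfg$msd_max_lag, origins = cfg$msd_origins,
    model = cfg$fit_model, n_dim = cfg$n_dim, window = cfg$fit_window,
    fit_drift = cfg$fit_drift, label = "channel hopping sweep")
  cmp <- compare_models(series)
  fit <- cmp$super_arrhenius
  ea <- activation_energy(fit, cfg$ea_temperatures) / 1000
  names(ea) <- sprintf("%g", cfg$ea_temperatures)
  if (!is.null(cfg$output_dir)) {
    dir.create(cfg$output_dir, recursive = TRUE, showWarnings = FALSE)
    write_rate_csv(series, file.path(cfg$output_dir,
                                     "diffusion_vs_temperature.csv"))
    write_fit_report(fit, file.path(cfg$output_dir, "fit_report.json"),
                     ea_temperatures = cfg$ea_temperatures, seed = cfg$seed,
                     settings = cfg[c("n_particles", "n_frames", "dt",
                                      "site_spacing", "barrier", "attempt_rate",
                                      "occupancy_decay", "fit_model", "n_dim")])
    say("artifacts written to %s", cfg$output_dir)
  }
  list(series = series, comparison = cmp, fit = fit,
       classification = classify_arrhenius(fit), ea_kJ_per_mol = ea)
}
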