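## Ensemble mean-squared displacement and diffusion-coefficient extraction.
##
## The default engine averages over all sliding time origins; for a frame lag
## m on an N-frame trajectory the per-particle average
##   msd(m) = 1/(N-m) * sum_k |r(k+m) - r(k)|^2
## is computed for all lags at once with the FFT autocorrelation identity
## (sum of squares via cumulative sums minus twice the autocorrelation), so
## the cost is O(N log N) per particle instead of O(N^2).

#' Mean-squared displacement curve
#'
#' @param lags Lag times in ps, strictly increasing, starting at 0.
#' @param msd Mean-squared displacement per lag, Angstrom^2, non-negative;
#'   `msd[1]` (lag 0) is exactly 0.
#' @param n_samples Number of (origin, particle) pairs averaged per lag.
#' @param by_particle Optional matrix of per-particle MSD curves
#'   (rows = lags, columns = particles) used for ensemble standard errors.
#' @return An `msd_curve` object.
#' @export
msd_curve <- function(lags, msd, n_samples, by_particle = NULL) {
  lags <- as.numeric(lags); msd <- as.numeric(msd)
  if (length(lags) != length(msd) || length(lags) != length(n_samples))
    stop_domain("lags, msd and n_samples must have equal length")
  if (any(diff(lags) <= 0)) stop_domain("lags must be strictly increasing")
  if (lags[1] != 0 || msd[1] != 0)
    stop_domain("an MSD curve starts at lag 0 with msd exactly 0")
  ## FFT round-off can leave tiny negatives on stationary data
  tiny <- msd < 0 & msd > -1e-8
  msd[tiny] <- 0
  if (any(msd < 0, na.rm = TRUE)) stop_domain("msd must be non-negative")
  structure(list(lags = lags, msd = msd, n_samples = as.numeric(n_samples),
                 by_particle = by_particle),
            class = "msd_curve")
}

#' @export
print.msd_curve <- function(x, ...) {
  cat(sprintf("<msd_curve> %d lags over 0-%.4g ps, msd up to %.4g A^2\n",
              length(x$lags), max(x$lags), max(x$msd, na.rm = TRUE)))
  invisible(x)
}

## multi-origin MSD for a frames x columns coordinate matrix (columns are
## particle/dimension pairs); returns (M+1) x ncol matrix of per-column MSD
msd_all_origins <- function(X, M) {
  N <- nrow(X)
  L <- stats::nextn(2L * N)
  Xp <- rbind(X, matrix(0, L - N, ncol(X)))
  Fx <- stats::mvfft(Xp)
  S2 <- Re(stats::mvfft(Fx * Conj(Fx), inverse = TRUE))[1:(M + 1L), , drop = FALSE] / L
  D <- X * X
  Q <- colSums(D)
  head_cum <- apply(D, 2, cumsum)
  tail_cum <- apply(D[N:1, , drop = FALSE], 2, cumsum)
  s1 <- matrix(rep(2 * Q, each = M + 1L), M + 1L, ncol(X))
  if (M >= 1) {
    s1[-1, ] <- s1[-1, , drop = FALSE] -
      head_cum[1:M, , drop = FALSE] - tail_cum[1:M, , drop = FALSE]
  }
  sweep(s1 - 2 * S2, 1, N - 0:M, "/")
}

#' Compute the ensemble mean-squared displacement
#'
#' For each lag, averages the squared 3-D displacement over the selected
#' particles and (by default) over all sliding time origins. A single-origin
#' mode reproduces the literal fixed-origin definition
#' `MSD(t) = 1/N * sum_n |x_n(t) - x_n(0)|^2`. With a residence `mask`, only
#' origin/endpoint pairs lying inside one contiguous in-residence interval of
#' at least 3 frames contribute.
#'
#' @param traj An unwrapped [trajectory()].
#' @param selection Particle ids, indices or logical mask; `NULL` = all.
#' @param max_lag Largest lag in ps; default (and maximum useful value for
#'   origin averaging) is half the trajectory duration, capped at the full
#'   duration.
#' @param origins `"all"` (sliding-origin average, default) or `"single"`.
#' @param mask Optional logical `n_frames x n_particles` residence matrix.
#' @param keep_particles Keep per-particle curves (needed by [fit_msd()] for
#'   particle-level standard errors)?
#' @return An [msd_curve()]; lags where no origin pair exists (possible under
#'   a mask) carry `NA` msd and `n_samples = 0`.
#' @export
compute_msd <- function(traj, selection = NULL, max_lag = NULL,
                        origins = c("all", "single"), mask = NULL,
                        keep_particles = FALSE) {
  stopifnot(inherits(traj, "trajectory"))
  origins <- match.arg(origins)
  if (traj$wrapped)
    stop_config("trajectory is wrapped; call unwrap_pbc() first")
  sel <- resolve_selection(traj, selection)
  N <- n_frames(traj)
  if (N < 2) stop_insufficient_data("MSD needs at least 2 frames")
  duration <- traj$times[N] - traj$times[1]
  if (is.null(max_lag)) max_lag <- duration / 2
  if (max_lag <= 0) stop_domain("max_lag must be > 0 ps")
  if (max_lag > duration + 1e-9 * duration)
    stop_domain("max_lag (%.4g ps) exceeds trajectory duration (%.4g ps)",
                max_lag, duration)
  M <- floor(max_lag / traj$dt + 1e-9)
  if (M < 1) stop_domain("max_lag is below one frame interval (%.4g ps)", traj$dt)
  lags <- (0:M) * traj$dt
  P <- length(sel)
  pos <- traj$positions[, sel, , drop = FALSE]

  if (!is.null(mask)) {
    if (!is.logical(mask) || !all(dim(mask) == c(N, n_particles(traj))))
      stop_domain("mask must be a logical n_frames x n_particles matrix")
    mask <- mask[, sel, drop = FALSE]
    return(msd_masked(pos, mask, M, lags, origins, keep_particles))
  }

  if (origins == "all") {
    X <- matrix(pos, nrow = N)                       # N x (P*3), dims blocked
    pp_dim <- msd_all_origins(X, M)
    by_particle <- pp_dim[, 1:P, drop = FALSE] +
      pp_dim[, P + 1:P, drop = FALSE] + pp_dim[, 2L * P + 1:P, drop = FALSE]
    n_samp <- (N - 0:M) * P
  } else {
    d1 <- pos[1:(M + 1), , 1, drop = FALSE] ; dim(d1) <- c(M + 1L, P)
    d2 <- pos[1:(M + 1), , 2, drop = FALSE] ; dim(d2) <- c(M + 1L, P)
    d3 <- pos[1:(M + 1), , 3, drop = FALSE] ; dim(d3) <- c(M + 1L, P)
    by_particle <- sweep(d1, 2, d1[1, ])^2 + sweep(d2, 2, d2[1, ])^2 +
      sweep(d3, 2, d3[1, ])^2
    n_samp <- rep(P, M + 1L)
  }
  m <- rowMeans(by_particle)
  m[1] <- 0
  by_particle[1, ] <- 0
  msd_curve(lags, m, n_samp,
            by_particle = if (keep_particles) by_particle else NULL)
}

## residence-interval MSD: origin and endpoint must lie inside one contiguous
## in-mask run; runs shorter than 3 frames are discarded
msd_masked <- function(pos, mask, M, lags, origins, keep_particles) {
  N <- dim(pos)[1]; P <- dim(pos)[2]
  sums <- numeric(M + 1L); counts <- numeric(M + 1L)
  by_particle <- if (keep_particles) matrix(NA_real_, M + 1L, P) else NULL
  for (p in seq_len(P)) {
    r <- rle(mask[, p])
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    keep <- r$values & r$lengths >= 3L
    psums <- numeric(M + 1L); pcounts <- numeric(M + 1L)
    for (i in which(keep)) {
      a <- starts[i]; b <- ends[i]; len <- b - a + 1L
      xs <- pos[a:b, p, , drop = FALSE]
      dim(xs) <- c(len, 3L)
      top <- if (origins == "all") min(M, len - 1L) else min(M, len - 1L)
      for (m in seq_len(top)) {
        if (origins == "all") {
          d <- xs[(m + 1):len, , drop = FALSE] - xs[1:(len - m), , drop = FALSE]
          psums[m + 1L] <- psums[m + 1L] + sum(d * d)
          pcounts[m + 1L] <- pcounts[m + 1L] + (len - m)
        } else {
          d <- xs[m + 1L, ] - xs[1L, ]
          psums[m + 1L] <- psums[m + 1L] + sum(d * d)
          pcounts[m + 1L] <- pcounts[m + 1L] + 1
        }
      }
      psums[1L] <- psums[1L] + 0
      pcounts[1L] <- pcounts[1L] + (if (origins == "all") len else 1)
    }
    sums <- sums + psums; counts <- counts + pcounts
    if (keep_particles) {
      v <- ifelse(pcounts > 0, psums / pcounts, NA_real_)
      v[1] <- if (pcounts[1] > 0) 0 else NA_real_
      by_particle[, p] <- v
    }
  }
  m <- ifelse(counts > 0, sums / counts, NA_real_)
  m[1] <- 0
  msd_curve(lags, m, counts, by_particle = by_particle)
}

#' Fit a diffusion coefficient to an MSD curve
#'
#' Least squares of `msd(t) = 2 n_dim D t + (V t)^2` over a lag window. The
#' default model `"paper_4Dt"` uses the 2-D prefactor `4 D t`; `"dim_2nDt"`
#' uses `2 n_dim D t` (6Dt for `n_dim = 3`), the physically grounded choice
#' for 3-D displacements. The two differ only by a constant rescaling of D
#' (2/3 between 4Dt and 6Dt); reports always carry the model tag. D is
#' converted to m^2 s^-1 via 1 A^2 ps^-1 = 1e-8 m^2 s^-1 (exact).
#'
#' When the curve carries per-particle MSDs, `stderr_D` is the particle-level
#' standard error: the ensemble least-squares estimate equals the mean of the
#' per-particle estimates (the fit is linear in the curve), so
#' `sd(D_i)/sqrt(P)` is an exact standard error under particle independence.
#' Otherwise a residual-based OLS standard error is reported (which assumes
#' independent lags and is usually optimistic).
#'
#' @param curve An [msd_curve()].
#' @param model `"paper_4Dt"` or `"dim_2nDt"`.
#' @param n_dim Dimensionality for `"dim_2nDt"` (default 3).
#' @param window `c(lag_min, lag_max)` in ps; default `[10%, 50%]` of the
#'   largest lag, excluding the short-time ballistic regime.
#' @param fit_drift Fit the `(Vt)^2` drift term? If the fitted `V^2` is
#'   negative the drift term is dropped and the pure-diffusion model refitted.
#' @return A `diffusion_estimate`: `D` (m^2 s^-1), `D_A2_per_ps`, `V`
#'   (A ps^-1), `fit_window`, `stderr_D` (m^2 s^-1), `msd_model`, `n_dim`,
#'   `clamped` (TRUE when a negative least-squares D was clamped to 0).
#' @export
fit_msd <- function(curve, model = c("paper_4Dt", "dim_2nDt"), n_dim = 3,
                    window = NULL, fit_drift = TRUE) {
  stopifnot(inherits(curve, "msd_curve"))
  model <- match.arg(model)
  if (model == "paper_4Dt") n_dim <- 2
  if (n_dim < 1) stop_domain("n_dim must be >= 1")
  if (is.null(window)) window <- c(0.1, 0.5) * max(curve$lags)
  if (length(window) != 2 || window[1] >= window[2])
    stop_domain("window must be c(lag_min, lag_max) with lag_min < lag_max")
  w <- which(curve$lags >= window[1] & curve$lags <= window[2] &
               curve$lags > 0 & !is.na(curve$msd))
  if (length(w) < 3)
    stop_insufficient_data("fit window contains %d lags; >= 3 required", length(w))
  t_ <- curve$lags[w]
  y <- curve$msd[w]
  pref <- 2 * n_dim

  solve_curve <- function(yy, drift) {
    X <- if (drift) cbind(t_, t_^2) else cbind(t_)
    unname(stats::lm.fit(X, yy)$coefficients)
  }
  drift <- isTRUE(fit_drift)
  beta <- solve_curve(y, drift)
  if (drift && beta[2] < 0) {       # negative V^2: drop the drift term
    drift <- FALSE
    beta <- solve_curve(y, FALSE)
  }
  D_a2 <- beta[1] / pref
  V <- if (drift) sqrt(max(beta[2], 0)) else 0
  clamped <- FALSE
  if (D_a2 < 0) { D_a2 <- 0; clamped <- TRUE
    warning("negative least-squares D clamped to 0", call. = FALSE) }

  if (!is.null(curve$by_particle)) {
    Dp <- apply(curve$by_particle[w, , drop = FALSE], 2,
                function(yy) solve_curve(yy, drift)[1]) / pref
    stderr_a2 <- stats::sd(Dp) / sqrt(length(Dp))
  } else {
    X <- if (drift) cbind(t_, t_^2) else cbind(t_)
    fit <- stats::lm.fit(X, y)
    df <- length(y) - ncol(X)
    stderr_a2 <- if (df > 0) {
      sigma2 <- sum(fit$residuals^2) / df
      sqrt(sigma2 * chol2inv(qr.R(qr(X)))[1, 1]) / pref
    } else NA_real_
  }
  structure(list(D = D_a2 * A2_PER_PS_TO_M2_PER_S,
                 D_A2_per_ps = D_a2,
                 V = unname(V),
                 fit_window = c(window[1], window[2]),
                 stderr_D = stderr_a2 * A2_PER_PS_TO_M2_PER_S,
                 stderr_D_A2_per_ps = stderr_a2,
                 msd_model = model, n_dim = n_dim,
                 n_lags = length(w), clamped = clamped),
            class = "diffusion_estimate")
}

#' @export
print.diffusion_estimate <- function(x, ...) {
  cat(sprintf("<diffusion_estimate> D = %.4g m^2/s (%.4g A^2/ps), V = %.4g A/ps [%s, window %.4g-%.4g ps]%s\n",
              x$D, x$D_A2_per_ps, x$V, x$msd_model,
              x$fit_window[1], x$fit_window[2],
              if (x$clamped) " (clamped)" else ""))
  invisible(x)
}

#' Assemble a diffusion-vs-temperature series from trajectory runs
#'
#' Runs MSD estimation and the diffusion fit on one trajectory per
#' temperature and assembles the fitted coefficients into a
#' [rate_series()] (`value_kind = "diffusion"`, values in m^2 s^-1) ready for
#' [fit_arrhenius()] / [fit_super_arrhenius()].
#'
#' @param runs List of `list(temperature = K, trajectory = , selection = )`
#'   entries (selection optional), one per temperature.
#' @param max_lag,origins,mask Passed to [compute_msd()].
#' @param model,n_dim,window,fit_drift Passed to [fit_msd()].
#' @param label Label for the resulting series.
#' @return A [rate_series()] with the per-run `diffusion_estimate`s attached
#'   as attribute `"estimates"`.
#' @export
diffusion_vs_temperature <- function(runs, max_lag = NULL,
                                     origins = "all", mask = NULL,
                                     model = "paper_4Dt", n_dim = 3,
                                     window = NULL, fit_drift = TRUE,
                                     label = "") {
  if (!is.list(runs) || length(runs) < 2)
    stop_insufficient_data("need >= 2 temperature runs, got %d", length(runs))
  temps <- vapply(runs, function(r) as.numeric(r$temperature), numeric(1))
  if (anyDuplicated(temps))
    stop_domain("duplicate temperature(s): %s K (one run per temperature)",
                paste(unique(temps[duplicated(temps)]), collapse = ", "))
  ests <- lapply(runs, function(r) {
    traj <- r$trajectory
    if (traj$wrapped && !is.null(traj$box)) traj <- unwrap_pbc(traj)
    curve <- compute_msd(traj, selection = r$selection, max_lag = max_lag,
                         origins = origins, mask = mask, keep_particles = TRUE)
    fit_msd(curve, model = model, n_dim = n_dim, window = window,
            fit_drift = fit_drift)
  })
  D <- vapply(ests, function(e) e$D, numeric(1))
  if (any(D <= 0))
    stop_domain("fitted D is not positive at T = %s K; cannot build a diffusion series",
                paste(temps[D <= 0], collapse = ", "))
  ord <- order(temps)
  series <- rate_series(temps[ord], D[ord], value_kind = "diffusion",
                        label = label)
  attr(series, "estimates") <- ests[ord]
  series
}
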