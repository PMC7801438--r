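## Deformed-Arrhenius kinetics: ln v = ln_pre + B/(RT) + C/(RT)^2.
## Convention (matching the channel fits): C < 0 <=> super-Arrhenius,
## i.e. Ea(T) = -B - 2C/(RT) decreases with increasing temperature.

#' Temperature-indexed rate or diffusion series
#'
#' Container for a set of positive rate constants or self-diffusion
#' coefficients measured at distinct absolute temperatures. Temperatures are
#' canonicalized ascending; exact duplicate temperatures are rejected (one
#' observation per temperature).
#'
#' @param temperatures Absolute temperatures in K, strictly positive.
#' @param values Positive rate constants (arbitrary unit) or diffusion
#'   coefficients (m^2 s^-1); a logarithm must exist.
#' @param value_kind `"rate"` or `"diffusion"`.
#' @param label Free-text label carried through to reports.
#' @return A `rate_series` object: list with `temperatures`, `values`,
#'   `value_kind`, `label`.
#' @examples
#' rate_series(c(280, 300, 320), c(1e-9, 3e-9, 7e-9), "diffusion")
#' @export
rate_series <- function(temperatures, values, value_kind = c("rate", "diffusion"),
                        label = "") {
  value_kind <- match.arg(value_kind)
  temperatures <- as.numeric(temperatures)
  values <- as.numeric(values)
  if (length(temperatures) != length(values))
    stop_domain("temperatures (%d) and values (%d) differ in length",
                length(temperatures), length(values))
  if (length(temperatures) < 2)
    stop_insufficient_data("a rate series needs at least 2 points, got %d",
                           length(temperatures))
  if (any(!is.finite(temperatures)) || any(temperatures <= 0))
    stop_domain("temperatures must be finite and strictly positive")
  if (anyDuplicated(temperatures))
    stop_domain("duplicate temperature(s): %s K (one observation per temperature)",
                paste(unique(temperatures[duplicated(temperatures)]), collapse = ", "))
  bad <- !is.finite(values) | values <= 0
  if (any(bad))
    stop_domain("non-positive or non-finite value at T = %s K (logarithm undefined)",
                paste(temperatures[bad], collapse = ", "))
  ord <- order(temperatures)
  structure(list(temperatures = temperatures[ord], values = values[ord],
                 value_kind = value_kind, label = label),
            class = "rate_series")
}

#' @export
print.rate_series <- function(x, ...) {
  cat(sprintf("<rate_series> %d %s values over %.4g-%.4g K%s\n",
              length(x$temperatures), x$value_kind,
              min(x$temperatures), max(x$temperatures),
              if (nzchar(x$label)) paste0(" [", x$label, "]") else ""))
  invisible(x)
}

## shared fit assembly ------------------------------------------------------

new_sa_fit <- function(ln_pre, B, C, r_squared, covariance, value_kind,
                       n, rss, label = "") {
  se <- sqrt(pmax(diag(covariance), 0))
  structure(list(ln_pre = ln_pre, B = B, C = C, r_squared = r_squared,
                 covariance = covariance, se = se, value_kind = value_kind,
                 n = n, rss = rss, label = label),
            class = "super_arrhenius_fit")
}

#' Build a deformed-Arrhenius parameter set directly
#'
#' Wraps known `(ln_pre, B, C)` parameters as a fit object so they can be fed
#' to [activation_energy()], [predict.super_arrhenius_fit()] or the rate-series
#' generator without refitting (e.g. published parameter tables).
#'
#' @param ln_pre Dimensionless ln of the pre-exponential factor (ln A or ln D0).
#' @param B Linear coefficient, J mol^-1.
#' @param C Quadratic coefficient, J^2 mol^-2; 0 gives a plain Arrhenius law.
#' @param value_kind `"rate"` or `"diffusion"`.
#' @param label Free-text label.
#' @return A `super_arrhenius_fit` with zero covariance and `r_squared = NA`.
#' @export
super_arrhenius_params <- function(ln_pre, B, C = 0,
                                   value_kind = c("rate", "diffusion"),
                                   label = "") {
  value_kind <- match.arg(value_kind)
  stopifnot(is.finite(ln_pre), is.finite(B), is.finite(C))
  new_sa_fit(ln_pre, B, C, NA_real_, matrix(0, 3, 3), value_kind,
             n = 0L, rss = NA_real_, label = label)
}

#' @export
print.super_arrhenius_fit <- function(x, ...) {
  cat(sprintf("<super_arrhenius_fit> ln_pre = %.4g, B = %.4g J/mol, C = %.4g J^2/mol^2\n",
              x$ln_pre, x$B, x$C))
  if (is.finite(x$r_squared))
    cat(sprintf("  R^2 (ln scale) = %.6f on n = %d points\n", x$r_squared, x$n))
  invisible(x)
}

## ln-scale OLS on basis {1, x, x^2}, x = 1/(RT); ncoef 2 drops the
## quadratic. The regression runs in the centered, scaled variable
## u = (x - mean(x))/sd(x) (raw powers of x ~ 4e-4 are catastrophically
## collinear) and the coefficients are transformed back exactly.
fit_ln_poly <- function(series, ncoef) {
  x <- 1 / (GAS_CONSTANT * series$temperatures)
  y <- log(series$values)
  m <- mean(x)
  s <- stats::sd(x)
  if (!is.finite(s) || s == 0)
    stop_singular("design matrix is singular: temperatures too close or degenerate")
  u <- (x - m) / s
  U <- cbind(1, u, u^2)[, seq_len(ncoef), drop = FALSE]
  qu <- qr(U)
  if (qu$rank < ncoef)
    stop_singular("design matrix is singular: temperatures too close or degenerate")
  fit <- lm.fit(U, y)
  alpha <- unname(fit$coefficients)
  rss <- sum(fit$residuals^2)
  tss <- sum((y - mean(y))^2)
  r2 <- if (tss > 0) 1 - rss / tss else as.numeric(rss <= 1e-24)
  df <- length(y) - ncoef
  cova <- matrix(0, ncoef, ncoef)
  if (df > 0) cova <- (rss / df) * chol2inv(qr.R(qu))
  ## exact back-transform u -> x: beta = A alpha
  A <- rbind(c(1, -m / s, m^2 / s^2),
             c(0, 1 / s, -2 * m / s^2),
             c(0, 0, 1 / s^2))[, seq_len(ncoef), drop = FALSE]
  beta3 <- as.vector(A %*% alpha)
  cov3 <- A %*% cova %*% t(A)
  list(beta = beta3, r2 = max(0, min(1, r2)), cov = cov3, rss = rss,
       n = length(y))
}

#' Fit a plain Arrhenius law
#'
#' Ordinary least squares of `ln(value)` on `x = 1/(RT)`: the model
#' `ln v = ln_pre + B/(RT)` with `B = -Ea`, so the (constant) activation
#' energy is `-B` in J mol^-1. The returned fit has `C = 0` exactly.
#'
#' @param series A [rate_series()].
#' @return A `super_arrhenius_fit` with fields `ln_pre`, `B` (J mol^-1),
#'   `C = 0`, `r_squared` (ln scale), `covariance` (3x3, quadratic row/column
#'   zero), `se`, `value_kind`, `n`, `rss`.
#' @examples
#' s <- generate_rate_series(5, -40000, 0, c(270, 300, 330), 0, seed = 1)
#' fit_arrhenius(s)
#' @export
fit_arrhenius <- function(series) {
  stopifnot(inherits(series, "rate_series"))
  if (length(series$temperatures) < 2)
    stop_insufficient_data("Arrhenius fit needs >= 2 points")
  f <- fit_ln_poly(series, 2L)
  new_sa_fit(f$beta[1], f$beta[2], 0, f$r2, f$cov, series$value_kind,
             f$n, f$rss, series$label)
}

#' Fit a deformed (super-)Arrhenius law with a quadratic 1/RT term
#'
#' Least squares of `ln(value)` on the basis `{1, 1/(RT), 1/(RT)^2}`:
#' `ln v = ln_pre + B/(RT) + C/(RT)^2`. With exactly 3 distinct temperatures
#' the quadratic interpolates the points. The temperature-dependent activation
#' energy implied by the fit is `Ea(T) = -B - 2C/(RT)` (see
#' [activation_energy()]); `C < 0` is the super-Arrhenius case (Ea falls as T
#' rises).
#'
#' @inheritParams fit_arrhenius
#' @return A `super_arrhenius_fit`; `r_squared` is computed on the ln scale.
#' @export
fit_super_arrhenius <- function(series) {
  stopifnot(inherits(series, "rate_series"))
  if (length(series$temperatures) < 3)
    stop_insufficient_data("super-Arrhenius fit needs >= 3 points, got %d",
                           length(series$temperatures))
  f <- fit_ln_poly(series, 3L)
  new_sa_fit(f$beta[1], f$beta[2], f$beta[3], f$r2, f$cov, series$value_kind,
             f$n, f$rss, series$label)
}

#' Temperature-dependent activation energy
#'
#' For a deformed-Arrhenius fit, `Ea(T) = -B - 2C/(RT)` in J mol^-1 (the
#' negative logarithmic derivative of the rate or diffusion coefficient with
#' respect to 1/RT). With `C = 0` this reduces to the constant Arrhenius
#' activation energy `-B`. Divide by 1000 for kJ mol^-1 at reporting time.
#'
#' @param fit A `super_arrhenius_fit`.
#' @param temperature Absolute temperature(s) in K, > 0; vectorized.
#' @return Activation energy in J mol^-1, same length as `temperature`.
#' @examples
#' p <- super_arrhenius_params(-33.77, 9.98e4, -1.58e8, "diffusion")
#' activation_energy(p, c(290, 300, 310)) / 1000   # kJ/mol
#' @export
activation_energy <- function(fit, temperature) {
  stopifnot(inherits(fit, "super_arrhenius_fit"))
  if (any(!is.finite(temperature)) || any(temperature <= 0))
    stop_domain("temperature must be finite and > 0 K")
  -fit$B - 2 * fit$C / (GAS_CONSTANT * temperature)
}

#' Classify the temperature dependence of a fit
#'
#' `C < -tolerance` is tagged `"super"` (activation energy decreases with
#' increasing temperature, the convex Arrhenius-plot deviation seen for
#' channel-confined water), `C > +tolerance` is `"sub"`, otherwise
#' `"arrhenius"`. The default tolerance is the fitted standard error of `C`,
#' so curvature smaller than its own uncertainty reads as plain Arrhenius.
#'
#' @param fit A `super_arrhenius_fit`.
#' @param tolerance Non-negative threshold on `C`, J^2 mol^-2; default the
#'   standard error of `C` (0 when unavailable).
#' @return `"super"`, `"sub"` or `"arrhenius"`.
#' @export
classify_arrhenius <- function(fit, tolerance = NULL) {
  stopifnot(inherits(fit, "super_arrhenius_fit"))
  if (is.null(tolerance)) {
    tolerance <- fit$se[3]
    if (!is.finite(tolerance)) tolerance <- 0
  }
  if (!is.finite(tolerance) || tolerance < 0)
    stop_domain("tolerance must be a non-negative number")
  if (fit$C < -tolerance) "super"
  else if (fit$C > tolerance) "sub"
  else "arrhenius"
}

#' Evaluate a deformed-Arrhenius fit forward
#'
#' Returns `exp(ln_pre + B/(RT) + C/(RT)^2)` — a rate constant or diffusion
#' coefficient in the units of the fitted series.
#'
#' @param object A `super_arrhenius_fit`.
#' @param temperature Absolute temperature(s) in K, > 0; vectorized.
#' @param ... Unused.
#' @return Predicted values, same length as `temperature`.
#' @export
predict.super_arrhenius_fit <- function(object, temperature, ...) {
  if (any(!is.finite(temperature)) || any(temperature <= 0))
    stop_domain("temperature must be finite and > 0 K")
  x <- 1 / (GAS_CONSTANT * temperature)
  exp(object$ln_pre + object$B * x + object$C * x^2)
}

#' Compare Arrhenius and super-Arrhenius fits on one series
#'
#' Fits both models and prefers the quadratic only when it improves the
#' adjusted (ln-scale) coefficient of determination; ties go to the simpler
#' Arrhenius law. The input series is never modified.
#'
#' @param series A [rate_series()] with at least 4 points (so the quadratic is
#'   not saturated).
#' @return A `model_comparison` list: `arrhenius`, `super_arrhenius` (fits),
#'   `rss` (named residual sums of squares), `adj_r_squared`, `delta_rss`,
#'   `preferred` (`"arrhenius"` or `"super_arrhenius"`).
#' @export
compare_models <- function(series) {
  stopifnot(inherits(series, "rate_series"))
  n <- length(series$temperatures)
  if (n < 4)
    stop_insufficient_data("model comparison needs >= 4 points, got %d", n)
  fa <- fit_arrhenius(series)
  fs <- fit_super_arrhenius(series)
  adj <- function(r2, p) 1 - (1 - r2) * (n - 1) / (n - p)
  adj_a <- adj(fa$r_squared, 2)
  adj_s <- adj(fs$r_squared, 3)
  preferred <- if (adj_s > adj_a + 1e-12) "super_arrhenius" else "arrhenius"
  structure(list(arrhenius = fa, super_arrhenius = fs,
                 rss = c(arrhenius = fa$rss, super_arrhenius = fs$rss),
                 adj_r_squared = c(arrhenius = adj_a, super_arrhenius = adj_s),
                 delta_rss = fa$rss - fs$rss,
                 preferred = preferred),
            class = "model_comparison")
}

#' @export
print.model_comparison <- function(x, ...) {
  cat(sprintf("<model_comparison> preferred: %s (adj R^2 %.6f vs %.6f)\n",
              x$preferred, x$adj_r_squared["arrhenius"],
              x$adj_r_squared["super_arrhenius"]))
  invisible(x)
}

#' Reference super-Arrhenius parameters for PFK-1 channel water diffusion
#'
#' Published deformed-Arrhenius parameter sets `(ln D0, B, C)` for water
#' self-diffusion in the three channel classes of the phosphofructokinase-1
#' tetramer (interface, porous and transient channels), fitted on the ln scale
#' over 260-340 K. These serve as generator inputs and worked examples; `B` is
#' in J mol^-1 and `C` in J^2 mol^-2.
#'
#' @return A data.frame with columns `channel`, `ln_pre`, `B`, `C`, `r_squared`.
#' @examples
#' p <- pfk1_reference_parameters()
#' f <- super_arrhenius_params(p$ln_pre[1], p$B[1], p$C[1], "diffusion")
#' activation_energy(f, 300) / 1000
#' @export
pfk1_reference_parameters <- function() {
  data.frame(
    channel = c("transient", "interface", "porous"),
    ln_pre = c(-33.77, -19.90, -17.61),
    B = c(9.98e4, 2.49e4, 8.31e3),
    C = c(-1.58e8, -6.40e7, -3.86e7),
    r_squared = c(0.9998, 0.9997, 0.9999),
    stringsAsFactors = FALSE
  )
}
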