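## Arrhenius / deformed-Arrhenius fitting and the derived activation energy.

test_that("rate_series canonicalizes and validates", {
  s <- rate_series(c(320, 280, 300), c(3, 1, 2), "rate")
  expect_equal(s$temperatures, c(280, 300, 320))
  expect_equal(s$values, c(1, 2, 3))
  expect_error(rate_series(300, 1), class = "hydrokin_insufficient_data")
  expect_error(rate_series(c(300, 300), c(1, 2)), class = "hydrokin_domain_error")
  expect_error(rate_series(c(280, 300), c(1, -2)), class = "hydrokin_domain_error")
  expect_error(rate_series(c(280, 300), c(1, 0)), class = "hydrokin_domain_error")
  expect_error(rate_series(c(-280, 300), c(1, 2)), class = "hydrokin_domain_error")
  ## non-positive value error names the offending temperature
  expect_error(rate_series(c(280, 300), c(1, 0)), "300")
})

test_that("fit_arrhenius recovers exact and degenerate generating parameters", {
  temps <- c(270, 300, 330)
  vals <- exp(5 - 40000 / (8.314 * temps))
  f <- fit_arrhenius(rate_series(temps, vals))
  expect_equal(f$ln_pre, 5, tolerance = 1e-10)
  expect_equal(f$B, -40000, tolerance = 1e-8)
  expect_identical(f$C, 0)
  ## constant series: zero slope
  f0 <- fit_arrhenius(rate_series(c(280, 300, 320), rep(exp(3), 3)))
  expect_equal(f0$ln_pre, 3, tolerance = 1e-12)
  expect_equal(f0$B, 0, tolerance = 1e-8)
  expect_equal(f0$r_squared, 1)
})

test_that("noisy Arrhenius fit matches the closed-form OLS oracle and truth", {
  temps <- seq(270, 340, by = 10)
  s <- generate_rate_series(2, -25000, 0, temps, noise_sigma = 0.02, seed = 42)
  f <- fit_arrhenius(s)
  o <- oracle_arrhenius_ols(s$temperatures, s$values)
  expect_equal(f$B, o$B, tolerance = 1e-10)
  expect_equal(f$ln_pre, o$ln_pre, tolerance = 1e-10)
  expect_equal(f$se[2], o$se_B, tolerance = 1e-8)
  expect_lt(abs(f$B - (-25000)), 3 * o$se_B)
})

test_that("fit_super_arrhenius recovers zero-noise channel-class parameters to machine precision", {
  p <- pfk1_reference_parameters()
  temps <- seq(270, 340, by = 10)
  for (i in seq_len(nrow(p))) {
    s <- generate_rate_series(p$ln_pre[i], p$B[i], p$C[i], temps, 0, seed = 1,
                              value_kind = "diffusion")
    f <- fit_super_arrhenius(s)
    expect_equal(f$ln_pre, p$ln_pre[i], tolerance = 1e-8)
    expect_equal(f$B, p$B[i], tolerance = 1e-8)
    expect_equal(f$C, p$C[i], tolerance = 1e-8)
    expect_equal(f$r_squared, 1, tolerance = 1e-12)
  }
})

test_that("three distinct points are interpolated exactly and match the normal-equation oracle", {
  withr::with_seed(11, {
    for (rep in 1:20) {
      temps <- sort(runif(3, 260, 350))
      if (min(diff(temps)) < 1) next
      vals <- exp(rnorm(3, 0, 2))
      s <- rate_series(temps, vals)
      f <- fit_super_arrhenius(s)
      expect_equal(predict(f, temps), vals, tolerance = 1e-8)
      expect_equal(f$r_squared, 1, tolerance = 1e-10)
      o <- oracle_quadratic_solve(temps, vals)
      expect_equal(f$ln_pre, o$ln_pre, tolerance = 1e-8)
      expect_equal(f$B, o$B, tolerance = 1e-8)
      expect_equal(f$C, o$C, tolerance = 1e-8)
    }
  })
})

test_that("plain-Arrhenius data keeps the quadratic coefficient within its uncertainty", {
  ## |C| < se(C) is a ~68% event per replicate under Gaussian noise, so the
  ## check is a replicate fraction, not a single draw
  temps <- seq(270, 340, by = 10)
  within_se <- vapply(1:50, function(seed) {
    s <- generate_rate_series(3, -30000, 0, temps, noise_sigma = 0.01,
                              seed = seed)
    f <- fit_super_arrhenius(s)
    abs(f$C) < f$se[3]
  }, logical(1))
  expect_gte(mean(within_se), 0.5)
})

test_that("arrhenius fit equals the C-constrained quadratic fit", {
  ## fit_arrhenius is exactly the quadratic model with C forced to 0
  temps <- seq(270, 340, by = 10)
  s <- generate_rate_series(1.5, -20000, 0, temps, noise_sigma = 0.05, seed = 3)
  fa <- fit_arrhenius(s)
  o <- oracle_arrhenius_ols(s$temperatures, s$values)
  expect_equal(fa$ln_pre, o$ln_pre, tolerance = 1e-10)
  expect_equal(fa$B, o$B, tolerance = 1e-10)
  expect_identical(fa$C, 0)
})

test_that("fit errors honour the preconditions", {
  s3 <- rate_series(c(280, 300, 320), c(1, 2, 3))
  expect_error(fit_super_arrhenius(rate_series(c(280, 300), c(1, 2))),
               class = "hydrokin_insufficient_data")
  expect_error(compare_models(s3), class = "hydrokin_insufficient_data")
})

test_that("activation energy follows Ea(T) = -B - 2C/(RT)", {
  ## worked values from the published channel parameter table (3 s.f. inputs)
  p <- super_arrhenius_params(0, 2.49e4, -6.40e7)
  expect_equal(activation_energy(p, 300) / 1000, 26.4, tolerance = 0.5 / 26.4)
  p2 <- super_arrhenius_params(0, 8.31e3, -3.86e7)
  expect_equal(activation_energy(p2, 290) / 1000, 23.7, tolerance = 0.5 / 23.7)
  ## Arrhenius limit: C = 0 gives exactly -B
  p3 <- super_arrhenius_params(0, -50000, 0)
  expect_identical(activation_energy(p3, 123.4), 50000)
  expect_error(activation_energy(p3, -1), class = "hydrokin_domain_error")
  expect_error(activation_energy(p3, 0), class = "hydrokin_domain_error")
})

test_that("Ea(T) is monotone in T with the sign of C", {
  grid <- seq(260, 340, by = 2)
  neg <- super_arrhenius_params(0, 1e4, -5e7)
  pos <- super_arrhenius_params(0, 1e4, +5e7)
  expect_true(all(diff(activation_energy(neg, grid)) < 0))
  expect_true(all(diff(activation_energy(pos, grid)) > 0))
})

test_that("classification maps the sign of C with a tolerance band", {
  expect_identical(classify_arrhenius(super_arrhenius_params(0, 1, -1.58e8)), "super")
  expect_identical(classify_arrhenius(super_arrhenius_params(0, 1, 0)), "arrhenius")
  ## generated sub-Arrhenius data propagates its positive curvature sign
  s <- generate_rate_series(-5, -10000, +1e7, seq(270, 340, 10), 0, seed = 2)
  fs <- fit_super_arrhenius(s)
  expect_gt(fs$C, 0)
  expect_identical(classify_arrhenius(fs), "sub")
  expect_error(classify_arrhenius(fs, tolerance = -1),
               class = "hydrokin_domain_error")
})

test_that("predict is the forward model and inverts zero-noise fitting", {
  f1 <- super_arrhenius_params(0, 0, 0)
  expect_equal(predict(f1, c(200, 300, 400)), c(1, 1, 1))
  temps <- seq(270, 340, by = 10)
  s <- generate_rate_series(-20, 5e4, -9e7, temps, 0, seed = 1)
  f <- fit_super_arrhenius(s)
  expect_equal(predict(f, temps), s$values, tolerance = 1e-8)
  ## diffusion rises with temperature for the transient-channel parameters
  ptab <- pfk1_reference_parameters()
  tr <- super_arrhenius_params(ptab$ln_pre[1], ptab$B[1], ptab$C[1], "diffusion")
  expect_gt(predict(tr, 310) / predict(tr, 290), 1)
  expect_true(all(diff(predict(tr, seq(270, 340, 5))) > 0))
  expect_error(predict(f, 0), class = "hydrokin_domain_error")
})

test_that("model comparison prefers the generating model", {
  temps <- seq(270, 340, by = 10)
  sup <- generate_rate_series(-33.7, 9.98e4, -1.6e8, temps, 0, seed = 1)
  cmp <- compare_models(sup)
  expect_identical(cmp$preferred, "super_arrhenius")
  expect_equal(cmp$super_arrhenius$r_squared, 1, tolerance = 1e-10)
  lin <- generate_rate_series(2, -30000, 0, temps, 0, seed = 1)
  cmpl <- compare_models(lin)
  ## exact linear data: quadratic adds nothing, simpler model wins the tie
  expect_identical(cmpl$preferred, "arrhenius")
  expect_lt(cmpl$delta_rss, 1e-12)
})

test_that("noisy super-Arrhenius data is preferred as quadratic in nearly all replicates", {
  temps <- seq(270, 340, by = 10)
  wins <- vapply(0:99, function(seed) {
    s <- generate_rate_series(-33.7, 9.98e4, -1.6e8, temps, 0.02, seed = seed)
    compare_models(s)$preferred == "super_arrhenius"
  }, logical(1))
  expect_gte(sum(wins), 90)
})

test_that("fit covariance is symmetric positive semidefinite", {
  s <- generate_rate_series(-10, 3e4, -5e7, seq(270, 340, 10), 0.03, seed = 9)
  f <- fit_super_arrhenius(s)
  expect_equal(f$covariance, t(f$covariance))
  ev <- eigen(f$covariance, symmetric = TRUE, only.values = TRUE)$values
  expect_true(all(ev > -1e-8 * max(abs(ev))))
  expect_true(f$r_squared >= 0 && f$r_squared <= 1)
})
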