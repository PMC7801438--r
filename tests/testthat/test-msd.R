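## Trajectory handling, periodic unwrapping, MSD computation and the
## diffusion-coefficient fit.

test_that("trajectory validates frame times and box", {
  pos <- array(0, dim = c(3, 2, 3))
  expect_error(trajectory(pos, times = c(0, 1, 1.5)), class = "hydrokin_domain_error")
  expect_error(trajectory(pos, times = c(0, 1)), class = "hydrokin_domain_error")
  expect_error(trajectory(pos, times = 0:2, box = c(-1, 10, 10)),
               class = "hydrokin_domain_error")
  tr <- trajectory(pos, times = 0:2, box = 10)
  expect_equal(tr$box, c(10, 10, 10))
  expect_equal(tr$dt, 1)
})

test_that("unwrap_pbc undoes single boundary crossings and is inverted by wrap_pbc", {
  ## particle crossing 9.5 -> 0.5 in a 10 A box continues to 10.5
  pos <- array(0, dim = c(2, 1, 3))
  pos[1, 1, ] <- c(9.5, 5, 5); pos[2, 1, ] <- c(0.5, 5, 5)
  tr <- trajectory(pos, times = 0:1, box = 10, wrapped = TRUE)
  un <- unwrap_pbc(tr)
  expect_equal(un$positions[2, 1, 1], 10.5)
  expect_false(un$wrapped)
  expect_equal(un$positions[1, 1, ], c(9.5, 5, 5))  # first frame unchanged

  ## no crossings: identity
  tr2 <- simulate_bulk_brownian(5, 4, box = 1000, D = 0.01, seed = 1)
  un2 <- unwrap_pbc(tr2)
  expect_equal(un2$positions, tr2$positions, tolerance = 1e-12)

  ## round trip on a trajectory with many crossings
  tr3 <- simulate_bulk_brownian(20, 50, box = 4, D = 0.5, seed = 2)
  expect_equal(wrap_pbc(unwrap_pbc(tr3))$positions, tr3$positions,
               tolerance = 1e-10)
  expect_error(unwrap_pbc(trajectory(pos, 0:1, box = NULL, wrapped = TRUE)),
               class = "hydrokin_config_error")
})

test_that("MSD of hand-checkable motions matches direct evaluation", {
  ## stationary particles: identically zero
  pos <- array(1.5, dim = c(10, 3, 3))
  tr <- trajectory(pos, times = 0:9)
  cv <- compute_msd(tr)
  expect_true(all(cv$msd == 0))

  ## one particle stepping +1 A per frame along x: msd(n dt) = n^2
  pos <- array(0, dim = c(5, 1, 3))
  pos[, 1, 1] <- 0:4
  tr <- trajectory(pos, times = 0:4)
  cv <- compute_msd(tr, max_lag = 2)
  expect_equal(cv$msd, c(0, 1, 4), tolerance = 1e-12)

  ## two particles displacing 1 A and 3 A in one frame: msd(dt) = (1+9)/2
  pos <- array(0, dim = c(2, 2, 3))
  pos[2, 1, 1] <- 1; pos[2, 2, 2] <- 3
  tr <- trajectory(pos, times = 0:1)
  cv <- compute_msd(tr, max_lag = 1)
  expect_equal(cv$msd[2], 5)
})

test_that("multi-origin engine equals the naive double-loop oracle", {
  withr::with_seed(21, {
    for (rep in 1:5) {
      nf <- sample(10:50, 1); np <- sample(2:10, 1)
      tr <- random_trajectory(nf, np, seed = rep * 101)
      M <- floor((nf - 1) / 2)
      cv <- compute_msd(tr, max_lag = M)
      expect_equal(cv$msd, oracle_msd_naive(tr$positions, M),
                   tolerance = 1e-10)
      expect_equal(cv$n_samples, (nf - 0:M) * np)
    }
  })
})

test_that("single-origin mode reproduces the literal fixed-origin definition", {
  tr <- random_trajectory(30, 6, seed = 5)
  cv <- compute_msd(tr, max_lag = 14, origins = "single")
  expect_equal(cv$msd, oracle_msd_single(tr$positions, 14), tolerance = 1e-12)
  expect_equal(cv$n_samples, rep(6, 15))
})

test_that("MSD is invariant under rigid translation and particle relabeling", {
  tr <- random_trajectory(40, 8, seed = 9)
  cv <- compute_msd(tr)
  ## common translation of every frame
  shifted <- tr$positions
  for (k in 1:3) shifted[, , k] <- shifted[, , k] + c(13, -7, 100)[k]
  cv_s <- compute_msd(trajectory(shifted, tr$times))
  expect_equal(cv_s$msd, cv$msd, tolerance = 1e-9)
  ## relabeling/permutation of particles
  perm <- c(5, 3, 8, 1, 7, 2, 6, 4)
  cv_p <- compute_msd(trajectory(tr$positions[, perm, , drop = FALSE], tr$times))
  expect_equal(cv_p$msd, cv$msd, tolerance = 1e-12)
})

test_that("msd(0) is exactly zero and n_samples is non-increasing in lag", {
  tr <- random_trajectory(60, 4, seed = 13)
  cv <- compute_msd(tr)
  expect_identical(cv$msd[1], 0)
  expect_true(all(diff(cv$n_samples) <= 0))
})

test_that("residence-mask MSD only uses pairs inside contiguous intervals", {
  ## particle in-channel for frames 1-5 and 8-12; step +1 A per frame
  pos <- array(0, dim = c(12, 1, 3))
  pos[, 1, 1] <- 0:11
  tr <- trajectory(pos, times = 0:11)
  mask <- matrix(FALSE, 12, 1)
  mask[c(1:5, 8:12), 1] <- TRUE
  cv <- compute_msd(tr, max_lag = 6, mask = mask)
  ## each run contributes lags 1-4 only; displacement is 1 A/frame in runs
  expect_equal(cv$msd[2:5], c(1, 4, 9, 16), tolerance = 1e-12)
  expect_equal(cv$n_samples[2:5], c(8, 6, 4, 2))
  expect_true(all(is.na(cv$msd[6:7])))
  expect_equal(cv$n_samples[6:7], c(0, 0))
  ## runs shorter than 3 frames are discarded entirely
  mask2 <- matrix(FALSE, 12, 1); mask2[1:2, 1] <- TRUE
  cv2 <- compute_msd(tr, max_lag = 3, mask = mask2)
  expect_true(all(cv2$n_samples == 0 | seq_along(cv2$n_samples) == 1))
})

test_that("selection handling rejects empty or unknown selections", {
  tr <- random_trajectory(10, 3, seed = 1)
  expect_error(compute_msd(tr, selection = character(0)),
               class = "hydrokin_domain_error")
  expect_error(compute_msd(tr, selection = "nosuch"),
               class = "hydrokin_domain_error")
  expect_error(compute_msd(tr, max_lag = 100), class = "hydrokin_domain_error")
})

test_that("fit_msd recovers exact linear and ballistic curves", {
  lags <- 0:50
  ## msd = 4 * 0.2 * t: paper-model D = 0.2 A^2/ps = 2e-9 m^2/s, V = 0
  cv <- msd_curve(lags, 4 * 0.2 * lags, rep(100, 51))
  est <- fit_msd(cv, model = "paper_4Dt")
  expect_equal(est$D_A2_per_ps, 0.2, tolerance = 1e-10)
  expect_equal(est$D, 2e-9, tolerance = 1e-10)
  expect_equal(est$V, 0, tolerance = 1e-8)
  ## same curve under the 3-D convention: D rescales by 2/3
  est6 <- fit_msd(cv, model = "dim_2nDt", n_dim = 3)
  expect_equal(est6$D_A2_per_ps, 0.2 * 2 / 3, tolerance = 1e-10)
  ## msd = (2t)^2: pure drift, V = 2, D = 0
  cvb <- msd_curve(lags, (2 * lags)^2, rep(100, 51))
  estb <- fit_msd(cvb, model = "paper_4Dt")
  expect_equal(estb$V, 2, tolerance = 1e-8)
  expect_equal(estb$D_A2_per_ps, 0, tolerance = 1e-8)
  ## all-zero curve: D = 0, V = 0, no error
  cvz <- msd_curve(lags, rep(0, 51), rep(100, 51))
  estz <- fit_msd(cvz)
  expect_equal(estz$D, 0)
  expect_equal(estz$V, 0)
  expect_error(fit_msd(cv, window = c(40, 41)),
               class = "hydrokin_insufficient_data")
})

test_that("Brownian simulation round trip recovers D within 3 standard errors", {
  tr <- simulate_bulk_brownian(300, 600, dt = 1, box = 60, D = 0.2, seed = 7)
  cv <- compute_msd(unwrap_pbc(tr), keep_particles = TRUE)
  est <- fit_msd(cv, model = "dim_2nDt", n_dim = 3, fit_drift = FALSE)
  expect_lt(abs(est$D_A2_per_ps - 0.2), 3 * est$stderr_D_A2_per_ps)
  ## unit conversion is exact
  expect_identical(est$D, est$D_A2_per_ps * 1e-8)
})

test_that("diffusion_vs_temperature assembles an ascending series and enforces run rules", {
  mk <- function(Tk, seed) list(
    temperature = Tk,
    trajectory = simulate_bulk_brownian(
      60, 200, box = 50, D = list(ln_pre = log(0.2) + 15000 / (8.314 * 300),
                                  B = -15000, C = 0),
      temperature = Tk, seed = seed))
  runs <- list(mk(320, 1), mk(280, 2))
  ser <- diffusion_vs_temperature(runs, model = "dim_2nDt", n_dim = 3,
                                  fit_drift = FALSE)
  expect_s3_class(ser, "rate_series")
  expect_identical(ser$value_kind, "diffusion")
  expect_equal(ser$temperatures, c(280, 320))
  expect_gt(ser$values[2], ser$values[1])   # D(320) > D(280), Eb = 15 kJ/mol
  expect_length(attr(ser, "estimates"), 2)
  expect_error(diffusion_vs_temperature(runs[1]),
               class = "hydrokin_insufficient_data")
  expect_error(diffusion_vs_temperature(list(mk(300, 1), mk(300, 2))),
               class = "hydrokin_domain_error")
})
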