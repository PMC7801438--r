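## Independent oracles: deliberately naive implementations used only to
## check the package's optimized paths.

R_GAS <- 8.314

## closed-form OLS of ln(v) on x = 1/(RT): slope and intercept from the
## covariance/variance formulas, no lm
oracle_arrhenius_ols <- function(temps, values) {
  x <- 1 / (R_GAS * temps)
  y <- log(values)
  b <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  a <- mean(y) - b * mean(x)
  se_b <- {
    res <- y - a - b * x
    sqrt(sum(res^2) / (length(y) - 2) / sum((x - mean(x))^2))
  }
  list(ln_pre = a, B = b, se_B = se_b)
}

## direct 3x3 normal-equation solve for the quadratic ln fit, done in the
## standardized variable z = (x - mean(x))/sd(x) for conditioning and
## expanded back analytically: with ln v = b0 + b1 z + b2 z^2,
## C = b2/s^2, B = b1/s - 2 b2 m/s^2, ln_pre = b0 - b1 m/s + b2 m^2/s^2
oracle_quadratic_solve <- function(temps, values) {
  x <- 1 / (R_GAS * temps)
  y <- log(values)
  m <- mean(x)
  s <- sd(x)
  z <- (x - m) / s
  Z <- cbind(1, z, z^2)
  b <- solve(t(Z) %*% Z, t(Z) %*% y)
  list(ln_pre = b[1] - b[2] * m / s + b[3] * m^2 / s^2,
       B = b[2] / s - 2 * b[3] * m / s^2,
       C = b[3] / s^2)
}

## naive O(frames^2) multi-origin MSD, scalar loops everywhere
oracle_msd_naive <- function(pos, max_lag_frames) {
  N <- dim(pos)[1]; P <- dim(pos)[2]
  msd <- numeric(max_lag_frames + 1)
  for (m in 0:max_lag_frames) {
    acc <- 0; cnt <- 0
    for (k in 1:(N - m)) {
      for (p in 1:P) {
        d <- pos[k + m, p, ] - pos[k, p, ]
        acc <- acc + sum(d^2)
        cnt <- cnt + 1
      }
    }
    msd[m + 1] <- acc / cnt
  }
  msd
}

## naive single-origin MSD (literal fixed-origin definition)
oracle_msd_single <- function(pos, max_lag_frames) {
  P <- dim(pos)[2]
  vapply(0:max_lag_frames, function(m) {
    mean(vapply(1:P, function(p) sum((pos[m + 1, p, ] - pos[1, p, ])^2),
                numeric(1)))
  }, numeric(1))
}

## brute-force point-to-segment water counting, scalar loops
oracle_count_waters <- function(waters, line, cutoff) {
  seg_dist <- function(p, a, b) {
    e <- b - a
    tt <- sum((p - a) * e) / sum(e^2)
    tt <- min(max(tt, 0), 1)
    sqrt(sum((p - a - tt * e)^2))
  }
  n <- 0L
  for (i in seq_len(nrow(waters))) {
    dmin <- Inf
    if (nrow(line) == 1) {
      dmin <- sqrt(sum((waters[i, ] - line[1, ])^2))
    } else {
      for (j in seq_len(nrow(line) - 1)) {
        dmin <- min(dmin, seg_dist(waters[i, ], line[j, ], line[j + 1, ]))
      }
    }
    if (dmin <= cutoff) n <- n + 1L
  }
  n
}

## random proper rotation matrix (QR with positive diagonal, det +1)
random_rotation <- function() {
  qrd <- qr(matrix(rnorm(9), 3, 3))
  Q <- qr.Q(qrd)
  Q <- Q %*% diag(sign(diag(qr.R(qrd))))
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  Q
}

## apply a rigid motion (rotation Q then translation v) to an n x 3 matrix
rigid <- function(m, Q, v) sweep(m %*% t(Q), 2, v, "+")

## small helper: random unwrapped trajectory
random_trajectory <- function(n_frames, n_particles, dt = 1, seed = 1) {
  withr::with_seed(seed, {
    pos <- array(rnorm(n_frames * n_particles * 3, sd = 2),
                 dim = c(n_frames, n_particles, 3))
    pos <- aperm(apply(pos, c(2, 3), cumsum), c(1, 2, 3))
    trajectory(pos, times = (seq_len(n_frames) - 1) * dt)
  })
}
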