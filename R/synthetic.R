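## Seeded generators with known ground truth: bulk Brownian water, barrier
## hopping in a channel, deformed-Arrhenius rate series, and channel-path
## fixtures with waters at known distances. All randomness is scoped with
## withr::with_seed, so generators are bit-reproducible and leave the global
## RNG untouched.

resolve_D_spec <- function(D, temperature) {
  if (is.list(D)) {
    stopifnot(all(c("ln_pre", "B") %in% names(D)))
    C <- if (is.null(D$C)) 0 else D$C
    x <- 1 / (GAS_CONSTANT * temperature)
    exp(D$ln_pre + D$B * x + C * x^2)
  } else {
    as.numeric(D)
  }
}

#' Simulate bulk Brownian water
#'
#' Independent Gaussian steps per axis with variance `2 D dt` (so the
#' expected 3-D MSD is `6 D t`), started uniformly in an orthorhombic box and
#' wrapped back into it every frame. `D` may be a constant in A^2 ps^-1 or a
#' deformed-Arrhenius specification `list(ln_pre, B, C)` evaluated at
#' `temperature` (result in A^2 ps^-1).
#'
#' @param n_particles,n_frames Counts, >= 1.
#' @param dt Frame interval, ps.
#' @param box Box edge length(s), Angstrom.
#' @param D Target diffusion coefficient (A^2 ps^-1), or `list(ln_pre, B, C)`.
#'   `D = 0` gives stationary particles.
#' @param temperature Temperature in K used to evaluate a `D(T)` spec.
#' @param seed Integer seed; same seed, same trajectory, bit for bit.
#' @return A wrapped [trajectory()].
#' @export
simulate_bulk_brownian <- function(n_particles, n_frames, dt = 1, box = 50,
                                   D = 0.2, temperature = 300, seed = 1) {
  if (n_particles < 1 || n_frames < 1) stop_domain("counts must be >= 1")
  if (dt <= 0) stop_domain("dt must be > 0")
  Dv <- resolve_D_spec(D, temperature)
  if (!is.finite(Dv) || Dv < 0)
    stop_domain("D(T) = %.4g is not a valid diffusion coefficient at T = %g K",
                Dv, temperature)
  box3 <- if (length(box) == 1) rep(box, 3) else box
  withr::with_seed(seed, {
    pos <- array(0, dim = c(n_frames, n_particles, 3))
    for (k in 1:3) {
      start <- runif(n_particles, 0, box3[k])
      if (n_frames >= 2) {
        steps <- matrix(rnorm((n_frames - 1) * n_particles,
                              sd = sqrt(2 * Dv * dt)),
                        n_frames - 1, n_particles)
        pos[, , k] <- apply(rbind(start, steps), 2, cumsum)
      } else {
        pos[1, , k] <- start
      }
    }
    wrap_pbc(trajectory(pos, times = (seq_len(n_frames) - 1) * dt, box = box3,
                        wrapped = FALSE))
  })
}

#' Simulate channel-confined water by barrier hopping
#'
#' Axial dynamics are discrete hops between sites spaced `site_spacing`
#' apart: each step hops with total probability
#' `p = attempt_rate * dt * exp(-barrier/(RT))` (direction +/- with equal
#' chance), so the barrier-free axial diffusion coefficient is
#' `site_spacing^2 * attempt_rate / 2`. Radial coordinates follow a
#' stationary Ornstein-Uhlenbeck jitter of scale `radial_sigma` (confinement
#' by the channel wall). With `occupancy_decay > 0`, a temperature-growing
#' fraction `f(T) = min(1, occupancy_decay * (T - 260)/100)` of particles is
#' released from the constrained state and performs free Brownian motion at
#' `bulk_D`: the constrained population thins faster with temperature than
#' the hopping rate grows, which is what bends the ensemble Arrhenius plot
#' into the super-Arrhenius (C < 0) shape.
#'
#' @param n_particles,n_frames Counts, >= 1.
#' @param dt Frame interval, ps.
#' @param site_spacing Distance between neighbouring potential minima, A.
#' @param barrier Hop barrier height Eb, J mol^-1, >= 0.
#' @param attempt_rate Attempt frequency k0, ps^-1, > 0.
#' @param radial_sigma Radial confinement scale, A.
#' @param radial_tau Radial relaxation time, ps.
#' @param occupancy_decay Temperature-thinning strength of the constrained
#'   population (0 = everyone stays confined).
#' @param bulk_D Free diffusion coefficient of released particles, A^2 ps^-1.
#' @param axis_length Channel axis length used to place starting sites, A.
#' @param temperature Temperature, K.
#' @param seed Integer seed.
#' @return An unwrapped [trajectory()] (no box); the logical attribute
#'   `"released"` marks which particles diffuse freely.
#' @export
simulate_channel_hopping <- function(n_particles, n_frames, dt = 1,
                                     site_spacing = 3, barrier = 25000,
                                     attempt_rate = 2000, radial_sigma = 0.5,
                                     radial_tau = 5, occupancy_decay = 0,
                                     bulk_D = 0.2, axis_length = 90,
                                     temperature = 300, seed = 1) {
  if (n_particles < 1 || n_frames < 1) stop_domain("counts must be >= 1")
  if (dt <= 0 || site_spacing <= 0 || attempt_rate <= 0)
    stop_domain("dt, site_spacing and attempt_rate must be > 0")
  if (barrier < 0) stop_domain("barrier must be >= 0")
  p_hop <- attempt_rate * dt * exp(-barrier / (GAS_CONSTANT * temperature))
  if (p_hop > 0.5)
    stop_domain(paste0("per-step hop probability %.3g > 0.5 at T = %g K: ",
                       "time step too large for the rate model"), p_hop, temperature)
  f_rel <- min(1, max(0, occupancy_decay * (temperature - 260) / 100))
  withr::with_seed(seed, {
    released <- runif(n_particles) < f_rel
    pos <- array(0, dim = c(n_frames, n_particles, 3))
    ## axial start sites along the channel
    sites <- sample.int(max(1L, floor(axis_length / site_spacing)) + 1L,
                        n_particles, replace = TRUE) - 1L
    start_ax <- sites * site_spacing
    nt <- sum(!released); nr <- sum(released)
    if (n_frames >= 2) {
      ns <- n_frames - 1
      if (nt > 0) {
        hop <- matrix(runif(ns * nt) < p_hop, ns, nt)
        dir <- matrix(sign(runif(ns * nt) - 0.5), ns, nt)
        steps <- site_spacing * hop * dir
        pos[, !released, 1] <- apply(rbind(start_ax[!released], steps), 2, cumsum)
      }
      if (nr > 0) {
        steps <- matrix(rnorm(ns * nr, sd = sqrt(2 * bulk_D * dt)), ns, nr)
        pos[, released, 1] <- apply(rbind(start_ax[released], steps), 2, cumsum)
      }
      ## radial: stationary OU for confined, free diffusion for released
      rho <- exp(-dt / radial_tau)
      innov_sd <- radial_sigma * sqrt(1 - rho^2)
      for (k in 2:3) {
        xk <- matrix(0, n_frames, n_particles)
        xk[1, ] <- rnorm(n_particles, sd = radial_sigma)
        for (f in 2:n_frames) {
          xk[f, ] <- rho * xk[f - 1, ] + rnorm(n_particles, sd = innov_sd)
        }
        if (nr > 0) {
          steps <- matrix(rnorm((n_frames - 1) * nr, sd = sqrt(2 * bulk_D * dt)),
                          n_frames - 1, nr)
          xk[, released] <- apply(rbind(xk[1, released], steps), 2, cumsum)
        }
        pos[, , k] <- xk
      }
    } else {
      pos[1, , 1] <- start_ax
      pos[1, , 2] <- rnorm(n_particles, sd = radial_sigma)
      pos[1, , 3] <- rnorm(n_particles, sd = radial_sigma)
    }
    traj <- trajectory(pos, times = (seq_len(n_frames) - 1) * dt,
                       box = NULL, wrapped = FALSE)
    attr(traj, "released") <- released
    traj
  })
}

#' Generate a rate series from the deformed-Arrhenius forward model
#'
#' `values = exp(ln_pre + B/(RT) + C/(RT)^2 + eps)` with
#' `eps ~ N(0, noise_sigma^2)` — multiplicative lognormal noise on the
#' natural scale.
#'
#' @param ln_pre,B,C Deformed-Arrhenius parameters (`B` J mol^-1, `C`
#'   J^2 mol^-2).
#' @param temperatures At least 2 distinct temperatures, K.
#' @param noise_sigma Standard deviation of the ln-scale noise, >= 0.
#' @param seed Integer seed.
#' @param value_kind,label Passed to [rate_series()].
#' @return A [rate_series()].
#' @export
generate_rate_series <- function(ln_pre, B, C, temperatures, noise_sigma = 0,
                                 seed = 1, value_kind = "rate", label = "") {
  if (noise_sigma < 0) stop_domain("noise_sigma must be >= 0")
  x <- 1 / (GAS_CONSTANT * temperatures)
  mu <- ln_pre + B * x + C * x^2
  vals <- withr::with_seed(seed, exp(mu + rnorm(length(mu), 0, noise_sigma)))
  rate_series(temperatures, vals, value_kind = value_kind, label = label)
}

#' Construct a channel fixture with waters at known distances
#'
#' Builds a smooth, gently curved random centerline rescaled to an exact
#' requested arc length, a positive radius profile, and a set of water
#' positions placed at controlled perpendicular offsets from the polyline so
#' that the true minimum distance of every water — hence the true count at
#' any cutoff — is known exactly. Out-of-channel placements are re-drawn
#' until their true distance exceeds the cutoff, so labels are guaranteed.
#'
#' @param n_points Centerline points, >= 2.
#' @param length Requested arc length, Angstrom.
#' @param radii Radius profile: vector of length `n_points`, a scalar, or
#'   `NULL` for a smooth generated profile.
#' @param n_waters Number of waters to place.
#' @param n_inside How many of them must lie within `cutoff`.
#' @param cutoff Distance cutoff in Angstrom the labels refer to.
#' @param lining_residues Optional lining passed to [channel_path()].
#' @param label Channel class tag.
#' @param seed Integer seed.
#' @return List: `path` ([channel_path()]), `waters` (`n_waters x 3` matrix),
#'   `distances` (true minimum distances to the polyline), `inside` (logical,
#'   `distances <= cutoff`), `cutoff`.
#' @export
make_channel_fixture <- function(n_points = 25, length = 90, radii = NULL,
                                 n_waters = 10, n_inside = 7, cutoff = 3,
                                 lining_residues = NULL,
                                 label = "other", seed = 1) {
  if (n_points < 2) stop_domain("n_points must be >= 2")
  if (n_inside > n_waters) stop_domain("n_inside cannot exceed n_waters")
  withr::with_seed(seed, {
    tt <- seq(0, 1, length.out = n_points)
    amp <- runif(2, 0.02, 0.06) * length
    freq <- runif(2, 0.5, 1.5)
    phase <- runif(2, 0, 2 * pi)
    pts <- cbind(length * tt,
                 amp[1] * sin(2 * pi * freq[1] * tt + phase[1]),
                 amp[2] * sin(2 * pi * freq[2] * tt + phase[2]))
    arc <- sum(sqrt(rowSums((pts[-1, ] - pts[-n_points, ])^2)))
    pts <- pts * (length / arc)          # exact requested arc length
    if (is.null(radii)) {
      radii <- 1.9 + 0.7 * sin(2 * pi * 2 * tt + runif(1, 0, 2 * pi))
    } else if (base::length(radii) == 1) {
      radii <- rep(radii, n_points)
    }
    path <- channel_path(pts, radii = radii,
                         lining_residues = lining_residues, label = label)

    place_water <- function(inside) {
      for (try in 1:200) {
        j <- sample.int(n_points - 1L, 1)
        s <- runif(1)
        q <- pts[j, ] + s * (pts[j + 1, ] - pts[j, ])
        e <- pts[j + 1, ] - pts[j, ]; e <- e / sqrt(sum(e^2))
        u <- rnorm(3); u <- u - sum(u * e) * e
        u <- u / sqrt(sum(u^2))
        off <- if (inside) runif(1, 0.25, 0.9 * cutoff)
               else runif(1, 1.2 * cutoff, 2.5 * cutoff)
        w <- q + off * u
        d <- min_dist_to_polyline(rbind(w), pts)
        if (inside && d <= cutoff) return(c(w, d))
        if (!inside && d > cutoff) return(c(w, d))
      }
      stop_domain("could not place a water with the requested label")
    }
    placed <- t(vapply(seq_len(n_waters),
                       function(i) place_water(i <= n_inside), numeric(4)))
    list(path = path,
         waters = placed[, 1:3, drop = FALSE],
         distances = placed[, 4],
         inside = placed[, 4] <= cutoff,
         cutoff = cutoff)
  })
}
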