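---
title: "Confined water kinetics: models, estimators and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Confined water kinetics: models, estimators and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hydrokin)
```

## The scientific problem

Water inside the channels of a folded enzyme does not diffuse like bulk
water. In the tetramer of phosphofructokinase-1 (PFK-1, the pacemaker enzyme
of glycolysis), channel-confined water hops between local potential minima
along narrow pathways, and the temperature dependence of its self-diffusion
coefficient `D(T)` deviates from the straight Arrhenius line: the Arrhenius
plot of `ln D` against `1/T` bends, and the apparent activation energy falls
as temperature rises. This *super-Arrhenius* signature connects the
molecular motion of channel water to the temperature response of cellular
respiration rates.

hydrokin implements the analysis chain needed to quantify that behaviour —
MSD-based diffusion estimation from trajectories, deformed-Arrhenius fitting
with a temperature-dependent activation energy, and channel hydration
statistics — together with seeded synthetic generators so the whole chain is
testable with known ground truth, without any molecular-dynamics output.

## The kinetic model

The deformed Arrhenius law adds a quadratic term in `1/RT` to the ordinary
rate law:

$$\ln v(T) = \ln v_0 + \frac{B}{RT} + \frac{C}{(RT)^2},$$

where `v` is a rate constant `k` or a diffusion coefficient `D`, and
`R = 8.314` J K⁻¹ mol⁻¹ throughout. The activation energy is the negative
logarithmic derivative with respect to `1/RT`:

$$E_a(T) = -B - \frac{2C}{RT},$$

a constant `-B` only when `C = 0`. Internally every energy is in J mol⁻¹;
kJ mol⁻¹ appears only at reporting boundaries (a deliberate guard against
unit mix-ups between `B` and `C` rows in published tables).

**Sign convention.** `C < 0` is classified `"super"`: `E_a` then decreases
with increasing temperature, which matches the published channel-water fits
(all have `C < 0` and are described as super-Arrhenius, with `E_a` falling
from 290 K to 310 K). Statements of the opposite convention exist in the
literature; hydrokin follows the one consistent with the parameter tables it
reproduces. `classify_arrhenius()` uses the fitted standard error of `C` as
its default tolerance, so curvature smaller than its own uncertainty reads
as plain Arrhenius.

**Numerics.** The fit is unweighted OLS on the ln scale (a weighting option
is deliberately absent: the reference fits state none). Raw powers of
`x = 1/RT ≈ 4×10⁻⁴` are catastrophically collinear, so the regression runs
in the standardized variable `u = (x - \bar x)/s_x` and the coefficients and
their covariance are transformed back exactly; with three distinct
temperatures the quadratic interpolates to near machine precision, which the
tests verify against an independent normal-equation solve. Series are
canonicalized ascending in temperature; exact duplicate temperatures are
rejected rather than averaged. `r_squared` is reported on the ln scale,
matching how published `R²` values for such fits are computed.

```{r}
p <- pfk1_reference_parameters()
fit <- super_arrhenius_params(p$ln_pre[1], p$B[1], p$C[1], "diffusion")
round(activation_energy(fit, c(290, 300, 310)) / 1000, 1)  # kJ/mol
```

## MSD estimation and the diffusion fit

The mean-squared displacement at frame lag `m` is averaged over particles
and, by default, over all sliding time origins:
`msd(m) = mean over k, n of |x_n(t_k + m Δt) - x_n(t_k)|²`. The literal
fixed-origin definition (`origins = "single"`) is also available; origin
averaging is the standard variance-reduction choice in single-particle
tracking and both modes are tested. The multi-origin engine uses the FFT
autocorrelation identity (cost `O(N log N)` per particle instead of
`O(N²)`), and is checked to 10⁻¹⁰ Å² against a naive double loop.

`fit_msd()` fits `msd(t) = 2 n_dim D t + (V t)²`. Two prefactor conventions
are exposed because both are used in practice:

* `"paper_4Dt"` (default): the `4Dt` form, kept for fidelity with analyses
  that apply it to 3-D displacements;
* `"dim_2nDt"` with `n_dim = 3`: the physically grounded `6Dt` for 3-D
  Brownian motion, used by this package's own simulation-recovery analyses.

The two differ only by the constant factor `2 n_dim / 4` on `D`; every
report carries the model tag. The default fit window is lags in 10–50% of
the maximum lag, excluding the short-time ballistic/jitter regime; negative
fitted `D` (possible under noise) is clamped to 0 with a warning flag, and a
negative fitted `V²` drops the drift term and refits pure diffusion. Unit
conversion is exact: 1 Å² ps⁻¹ = 10⁻⁸ m² s⁻¹.

**Standard errors.** Because the least-squares estimate is linear in the MSD
curve, the ensemble estimate equals the mean of per-particle estimates
fitted with the same design. When per-particle curves are kept
(`keep_particles = TRUE`), `stderr_D` is `sd(D_i)/√P` — exact under particle
independence, and honest where a residual-based OLS error would be
optimistic (MSD values at neighbouring lags are strongly correlated).
Residence-interval MSD for channel waters restricts origin/endpoint pairs to
one contiguous in-channel interval and discards intervals shorter than 3
frames (a rule this package fixes, since none is stated in the reference
analyses).

Periodic-boundary unwrapping applies the minimum-image convention to every
frame-to-frame displacement; a real jump beyond half a box edge per frame is
indistinguishable from a wrap, so the convention is taken as the definition
rather than a heuristic, and non-uniform frame times are an error rather
than being resampled.

## The synthetic generators as study conditions

The generators emulate the three ingredients of the original study —
bulk water, channel-confined water, and published-parameter rate series —
with defaults chosen once as the study conditions:

* **Bulk Brownian** (`simulate_bulk_brownian`): Gaussian steps of variance
  `2 D dt` per axis, wrapped into the box. The reference analyses use
  `D = 0.2` Å² ps⁻¹ (2×10⁻⁹ m² s⁻¹, the right order for ambient water) at
  500 particles × 2000 frames — a desk-scale stand-in for the ~56,000-water
  MD boxes of the original study.
* **Channel hopping** (`simulate_channel_hopping`): axial hops of
  `site_spacing = 3` Å (a hydrogen-bond-network site distance) with total
  per-step probability `p = k₀ dt e^{-E_b/RT}`; the barrier-free limit has
  the exact 1-D random-walk coefficient `D = a² k₀ / 2`, which is what the
  validity guard `p ≤ 0.5` protects. Defaults `E_b = 25` kJ/mol (mid-range
  of the published channel barriers, 18–33 kJ/mol) and `k₀ = 2000` ps⁻¹
  keep hops observable across 270–340 K at `dt = 1` ps. Radial confinement
  is a stationary Ornstein–Uhlenbeck jitter (`radial_sigma = 0.5` Å), whose
  MSD plateau (~1 Å²) is negligible inside the default fit window.
* **Occupancy thinning.** The proposed mechanism for the super-Arrhenius
  bend is that the constrained water population thins with temperature
  faster than its hopping rate grows. No quantitative law is published, so
  the generator makes the mechanism explicit and simple: a fraction
  `f(T) = min(1, occupancy_decay · (T - 260)/100)` of particles is released
  to bulk-like free diffusion (`bulk_D = 0.2` Å² ps⁻¹). With
  `occupancy_decay = 1` the ensemble `D(T)` then rises only ~4–8× over
  270–340 K while the pure hopping term would rise ~10×, the Arrhenius plot
  bends convex (`C < 0` around -1×10⁸ J² mol⁻², the magnitude seen for the
  transient channel), and `E_a(290) > E_a(310)` — exactly the qualitative
  signature the analysis must detect. `occupancy_decay` is a free modelling
  knob, documented as such; the acceptance surface is sign/ordering
  recovery, never absolute `D` values.
* **Rate series** (`generate_rate_series`): the forward deformed-Arrhenius
  model with multiplicative lognormal noise; at 2% noise and 8 temperatures
  the sign of `C` and the linear coefficient `B` are comfortably
  recoverable, which the Monte-Carlo tests quantify (100 seeded
  replicates).
* **Channel fixtures** (`make_channel_fixture`): a gently curved random
  centerline rescaled to an *exact* requested arc length, with waters placed
  at controlled perpendicular offsets so the true minimum distance of every
  water is known; out-of-channel placements are re-drawn until their true
  distance exceeds the cutoff, so in/out labels are guaranteed, making exact
  count verification possible.

What the generators deliberately do not emulate: real water physics
(hydrogen-bond networks, TIP4P-class force fields), channel-wall chemistry,
or the absolute diffusion coefficients and water counts of the original MD
trajectories. Passing tests therefore demonstrate that the *estimators*
recover known ground truth under realistic noise — not that the synthetic
world reproduces the original system's absolute numbers.

## Channel hydration statistics

The water-count rule is "within 3 Å of the channel center", interpreted as
distance to the centerline *polyline* (minimum over point-to-segment
distances, boundary inclusive) — counting waters all along the channel, not
around a single midpoint. Counting is verified exactly against a brute-force
oracle. Published channel "widths" are treated as diameters, so
`channel_bottleneck()` reports both the minimum radius and `width = 2r`
(first occurrence on ties). Hydropathy uses the Kyte–Doolittle scale
normalized by 4.5 into `[-1, 1]`; published channel hydropathy ranges
(−1.07 to 0.80) sit essentially on that scale, and the small overshoot
suggests the original tool's normalization differs slightly — the package
keeps the clean `[-1, 1]` convention. Lining residues carry no coordinates,
so profile segments are assigned by residue order. Water identity is the
caller's contract: the module counts whatever particle ids it is given
(conventionally water oxygens) and never parses chemistry.
`water_count_stats()` uses the sample standard deviation (n−1) over strided
frames, with the default stride aiming at ~10 frames spaced 100 ps apart —
the sampling used for the published per-channel water counts (11 ± 4,
17 ± 3, 15 ± 9 for the interface/porous/transient classes).

## Problem sizes and reproducibility

The simulation-recovery analyses use 500 × 2000 (bulk) and 120 × 400 × 8
temperatures (hopping sweeps), sizes at which the particle-level standard
errors make 3σ recovery checks decisive while a full Monte-Carlo run (100
seeded replicates) completes in minutes on one CPU. All generator calls are
seeded through `withr::with_seed`, so every analysis is bit-reproducible and
leaves the global RNG untouched; `scripts/acceptance.R` derives every
sub-seed from its single `--seed` argument, and identical configuration plus
seed gives byte-identical pipeline artifacts.

## Known limitations

* Channel *detection* is out of scope: `channel_path` objects are inputs
  (from JSON/CSV or the fixture generator), not computed from structures.
* The deformed-Arrhenius quadratic is a local description over the fitted
  temperature range; extrapolating `E_a(T)` far outside 260–340 K can cross
  zero and is not meaningful.
* The per-particle standard error assumes independent particles; in a dense
  simulated liquid with interactions (not the case for these generators)
  it would understate the true error.
* `value_kind` is a tag, not a unit system: diffusion series are expected in
  m² s⁻¹ and rate series in any fixed positive unit, and the fits are
  invariant to that choice up to `ln_pre`.
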