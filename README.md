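# hydrokin

Temperature dependence of confined water dynamics: MSD-based diffusion
estimation, super-Arrhenius kinetics fitting, and enzyme-channel hydration
statistics.

## The problem

Water confined in the nano-channels of a folded enzyme — the motivating
system is the phosphofructokinase-1 (PFK-1) tetramer, glycolysis'
rate-limiting "pacemaker" — diffuses by hopping over potential barriers
rather than moving freely. Its self-diffusion coefficient `D(T)` then
deviates from the Arrhenius law: the plot of `ln D` against `1/T` bends
("super-Arrhenius" behaviour), and the apparent activation energy decreases
as temperature rises. Quantifying that bending links channel-water motion to
the temperature response of respiration rates.

hydrokin is for computational biophysicists and enzyme-kinetics modellers
who need this analysis chain as tested, reusable components:

* **`trajectory` / MSD** — ensemble mean-squared displacement with sliding
  time origins (FFT engine, naive-oracle-verified), periodic-boundary
  unwrapping, residence-interval masking, and diffusion fits
  `msd(t) = 2 n_dim D t + (Vt)^2` with particle-level standard errors.
* **Kinetics** — fits of temperature-indexed rate or diffusion series to

  `ln v = ln v0 + B/(RT) + C/(RT)^2`,  `Ea(T) = -B - 2C/(RT)`,

  with `R = 8.314` J K⁻¹ mol⁻¹; `C < 0` means super-Arrhenius (Ea falls as
  T rises). Includes Arrhenius-vs-quadratic model comparison and
  sign-of-curvature classification with an uncertainty-based tolerance.
* **Channel hydration** — centerline arc length, bottleneck radius/width,
  normalized Kyte–Doolittle hydropathy profiles, and per-frame counts of
  waters within a cutoff of the centerline polyline (exact,
  brute-force-verified).
* **Synthetic generators** — seeded Brownian boxes, barrier-hopping channel
  water with temperature-thinned occupancy (the mechanism that produces the
  super-Arrhenius bend), deformed-Arrhenius rate series, and channel
  fixtures with waters at known distances. Every analysis stage is testable
  offline with known ground truth.

File formats: extended XYZ and minimal multi-MODEL PDB for trajectories,
2-column CSV for rate tables, JSON/CSV for channel paths, JSON fit reports
with unit-tagged keys.

## Worked example

Fit a noisy channel-water diffusion series and read off the
temperature-dependent activation energy:

```r
library(hydrokin)

## temperature-indexed diffusion series for the transient channel,
## generated from the reference parameters with 2% lognormal noise
p <- pfk1_reference_parameters()
series <- generate_rate_series(p$ln_pre[1], p$B[1], p$C[1],
                               temperatures = seq(270, 340, by = 10),
                               noise_sigma = 0.02, seed = 1,
                               value_kind = "diffusion", label = "transient")
series
#> <rate_series> 8 diffusion values over 270-340 K [transient]

cmp <- compare_models(series)
cmp
#> <model_comparison> preferred: super_arrhenius (adj R^2 0.970928 vs 0.999524)

fit <- cmp$super_arrhenius
fit
#> <super_arrhenius_fit> ln_pre = -34.09, B = 1.016e+05 J/mol, C = -1.605e+08 J^2/mol^2
#>   R^2 (ln scale) = 0.999660 on n = 8 points

round(activation_energy(fit, c(290, 300, 310)) / 1000, 1)
#> [1] 31.5 27.1 22.9
classify_arrhenius(fit)
#> [1] "super"
```

The quadratic model is preferred over the straight Arrhenius line, the
fitted curvature is negative, and the activation energy falls from
31.5 kJ/mol at 290 K to 22.9 kJ/mol at 310 K — the super-Arrhenius
signature of channel-confined water. `B` and `C` recover the generating
parameters (9.98×10⁴ and −1.58×10⁸) within the 2% noise.

## Analysis workflow

The `analysis/` scripts chain the package into the full study, writing
tables under `results/`:

1. `01_rate_refits.R` — deformed-Arrhenius refits of the three channel
   classes (interface/porous/transient) and their Ea(290/300/310 K).
2. `02_bulk_diffusion.R` — bulk Brownian reference sweep: stays Arrhenius,
   recovers the generator barrier.
3. `03_channel_sweep.R` — channel-hopping sweeps through the full pipeline:
   confined hopping recovers its 25 kJ/mol barrier; temperature-thinned
   occupancy bends the plot super-Arrhenius.
4. `04_channel_hydration.R` — channel geometry, hydropathy profiles and
   exact water counts on constructed fixtures.

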