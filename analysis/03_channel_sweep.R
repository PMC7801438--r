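#!/usr/bin/env Rscript
## Stage 3 — channel-confined water: hopping sweeps and the super-Arrhenius
## signature. The headline analysis.
##
## Two temperature sweeps of the channel-hopping generator (Eb = 25 kJ/mol,
## site spacing 3 A), run through the full pipeline (trajectories -> MSD ->
## D(T) -> model comparison):
##   (a) occupancy_decay = 0 — everyone stays confined; ln D vs 1/RT should
##       be a straight line whose slope returns the barrier;
##   (b) occupancy_decay = 1 — the constrained population thins with
##       temperature; the plot should bend convex (C < 0) with Ea falling
##       between 290 and 310 K, the signature seen for channel waters.
##
## Finding: (a) recovers the 25 kJ/mol barrier within a few percent with
## insignificant curvature; (b) classifies super with Ea(290) > Ea(310) and
## D spanning roughly an order of magnitude over the sweep — the qualitative
## behaviour of enzyme-channel water.

suppressMessages(library(hydrokin))
out_dir <- "results"
dir.create(out_dir, showWarnings = FALSE)
seed <- 1L

run_sweep <- function(decay, tag) {
  cfg <- pipeline_config(temperatures = seq(270, 340, by = 10),
                         n_particles = 120, n_frames = 400,
                         barrier = 25000, occupancy_decay = decay,
                         output_dir = file.path(out_dir, tag),
                         seed = seed, log_level = "quiet")
  run_pipeline(cfg)
}

confined <- run_sweep(0, "03_confined")
thinned <- run_sweep(1, "03_thinned")

fa <- confined$comparison$arrhenius
cat("Sweep (a): occupancy_decay = 0 (fully confined hopping)\n")
cat(sprintf("  Arrhenius slope -> Eb = %.2f kJ/mol (input 25.0)\n", -fa$B / 1000))
cat(sprintf("  curvature C = %.3g +/- %.3g, preferred model: %s\n",
            confined$fit$C, confined$fit$se[3], confined$comparison$preferred))

cat("\nSweep (b): occupancy_decay = 1 (temperature-thinned occupancy)\n")
cat(sprintf("  classification: %s; C = %.3g J^2/mol^2\n",
            thinned$classification, thinned$fit$C))
cat(sprintf("  Ea(290/300/310 K) = %.1f / %.1f / %.1f kJ/mol\n",
            thinned$ea_kJ_per_mol[1], thinned$ea_kJ_per_mol[2],
            thinned$ea_kJ_per_mol[3]))
cat(sprintf("  D spans %.3g - %.3g m^2/s over the sweep\n",
            min(thinned$series$values), max(thinned$series$values)))
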