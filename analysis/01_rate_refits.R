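#!/usr/bin/env Rscript
## Stage 1 — deformed-Arrhenius refits of channel-water diffusion series.
##
## Generates D(T) series over 270-340 K from the reference parameter sets of
## the three PFK-1 channel classes (zero-noise, then 2% lognormal noise),
## refits both the plain Arrhenius and the quadratic deformed model, and
## tabulates the recovered parameters and the temperature-dependent
## activation energies Ea(290/300/310 K).
##
## Finding: all three channel classes refit as super-Arrhenius (C < 0) with
## Ea decreasing by several kJ/mol between 290 and 310 K; the transient
## channel is the most temperature-sensitive. With 2% noise the quadratic
## model is still preferred and the sign of C is stable.

suppressMessages(library(hydrokin))
out_dir <- "results"
dir.create(out_dir, showWarnings = FALSE)
seed <- 1L
temps <- seq(270, 340, by = 10)
p <- pfk1_reference_parameters()

rows <- do.call(rbind, lapply(seq_len(nrow(p)), function(i) {
  exact <- generate_rate_series(p$ln_pre[i], p$B[i], p$C[i], temps, 0,
                                seed = seed, value_kind = "diffusion",
                                label = p$channel[i])
  noisy <- generate_rate_series(p$ln_pre[i], p$B[i], p$C[i], temps, 0.02,
                                seed = seed + i, value_kind = "diffusion")
  f <- fit_super_arrhenius(exact)
  fn <- fit_super_arrhenius(noisy)
  cmp <- compare_models(noisy)
  data.frame(channel = p$channel[i],
             ln_pre = f$ln_pre, B_J_mol = f$B, C_J2_mol2 = f$C,
             r_squared = f$r_squared,
             Ea290_kJ = activation_energy(f, 290) / 1000,
             Ea300_kJ = activation_energy(f, 300) / 1000,
             Ea310_kJ = activation_energy(f, 310) / 1000,
             classification = classify_arrhenius(f),
             noisy_C_J2_mol2 = fn$C,
             noisy_preferred = cmp$preferred)
}))
write.csv(rows, file.path(out_dir, "01_channel_refits.csv"), row.names = FALSE)

cat("Refit of the three channel classes (zero-noise generation, 8 temps):\n")
print(rows[, c("channel", "B_J_mol", "C_J2_mol2", "Ea290_kJ", "Ea300_kJ",
               "Ea310_kJ", "classification")], row.names = FALSE)
cat(sprintf("\nAll classified '%s'; Ea(290) - Ea(310) spans: %s kJ/mol\n",
            paste(unique(rows$classification), collapse = "/"),
            paste(sprintf("%.1f", rows$Ea290_kJ - rows$Ea310_kJ), collapse = ", ")))
cat(sprintf("With 2%% noise the quadratic model is preferred for %d/%d channels.\n",
            sum(rows$noisy_preferred == "super_arrhenius"), nrow(rows)))
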