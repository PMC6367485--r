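#!/usr/bin/env Rscript
# Stage 5 — shell chemistry: titration plateau and grafting density, brush
# consistency with the measured shell, payload per particle, and the
# equilibrium-growth-model surface-area ratio.

suppressMessages(library(nanoshell))
fix <- "results/fixtures"
out <- "results"
cfg <- default_config(1)

## titration: plateau density and thickness
ser <- read.csv(file.path(fix, "titration.csv"))
stopifnot_valid_csv(ser, "titration")
gold <- list(core_diameter_nm = 100, particle_concentration_per_uL = 5.6e6,
             volume_uL = 20)
res <- analyze_titration(ser, gold_spec = gold,
                         brush_params = list(n_monomers = cfg$chemistry$n_monomers,
                                             monomer_nm = cfg$chemistry$monomer_nm))
cat(sprintf("titration: saturation at step %d, plateau density %.3f PEG/nm2, thickness %.1f nm\n",
            res$saturation_step, res$plateau_density, res$plateau_thickness))

## brush consistency at the equilibrium density
L_brush <- brush_thickness(cfg$chemistry$n_monomers, cfg$chemistry$monomer_nm,
                           cfg$chemistry$equilibrium_density_per_nm2)
shell <- read.csv(file.path(out, "shell_estimate.csv"))
cat(sprintf("brush model at D* = %.2f PEG/nm2: L = %.1f nm (measured shell %.1f nm)\n",
            cfg$chemistry$equilibrium_density_per_nm2, L_brush, shell$thickness_nm))

## payload per particle across the polyplex populations
f_dna <- dna_mass_fraction(cfg$chemistry$np_ratio)
params <- payload_params(cfg$chemistry$core_density_ug_per_uL,
                         cfg$chemistry$na_mw_g_per_mol, f_dna)
rows <- lapply(c(7, 10), function(conj) {
  pop <- read_populations_csv(file.path(fix, sprintf("polyplex_conj%02d.csv", conj)))[[1]]
  fit <- fit_lognormal(pop$diameters)
  data.frame(conjugation_pct = conj, median_core_nm = fit$median_nm,
             payload_at_median = payload_count(fit$median_nm, params))
})
chem <- do.call(rbind, rows)

## growth model: surface-area ratio 7% vs 10%
chem$area_ratio_7_vs_10 <- surface_area_ratio(7, 10)
ratio_diam <- chem$median_core_nm[chem$conjugation_pct == 10] /
  chem$median_core_nm[chem$conjugation_pct == 7]
write.csv(chem, file.path(out, "chemistry.csv"), row.names = FALSE)

cat(sprintf("DNA mass fraction at N/P = %g: f = %.3f\n", cfg$chemistry$np_ratio, f_dna))
print(chem)
cat(sprintf("surface-area ratio from sampled core diameters: %.3f (model: 0.7)\n",
            ratio_diam))
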