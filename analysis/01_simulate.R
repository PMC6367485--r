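#!/usr/bin/env Rscript
# Stage 1 — generate the synthetic study inputs: the 11-member gold core
# series (bare and PEGylated), AFM topographs of a 50-nm member, DLS
# correlograms for every member, a PEGylation titration of the 100-nm
# member, and polyplex core populations at 7% and 10% conjugation.
# Everything is seeded; re-running reproduces byte-identical CSVs.

suppressMessages(library(nanoshell))
seed <- 1
out <- "results/fixtures"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

cfg <- default_config(seed)

## gold reference series (constant relative SD across nominal sizes)
pops <- gen_gold_series(cfg$gold$nominal_nm, cfg$gold$rel_sd, cfg$gold$n, seed)
write_populations_csv(pops, file.path(out, "populations.csv"))
manifest <- data.frame(label = names(pops),
                       nominal_nm = cfg$gold$nominal_nm,
                       n = cfg$gold$n, rel_sd = cfg$gold$rel_sd, seed = seed)
write.csv(manifest, file.path(out, "series_manifest.csv"), row.names = FALSE)
stopifnot(nrow(manifest) == length(pops))

## AFM topographs: four fields of the 50-nm member (several hundred particles)
dls <- dls_config(beta = cfg$dls$beta)
for (i in 1:4) {
  sub <- gen_core_population(50, cfg$gold$rel_sd, 80, seed = 100 * seed + i)
  topo <- gen_afm_topograph(sub, pixel_nm = cfg$afm$pixel_nm, field_nm = 1600,
                            tilt_nm_per_px = cfg$afm$tilt_nm_per_px,
                            noise_sd_nm = cfg$afm$noise_sd_nm,
                            seed = 200 * seed + i)
  write_topograph(topo, file.path(out, sprintf("topograph_%02d.txt", i)))
}

## DLS correlograms: bare and RPP-functionalized (L = 17 nm) series
for (i in seq_along(pops)) {
  bare <- simulate_g2(pops[[i]], dls, noise_sd = cfg$dls$noise_sd,
                      seed = 300 * seed + i)
  func <- simulate_g2(functionalize(pops[[i]], 17)$hydrodynamic_diameters, dls,
                      noise_sd = cfg$dls$noise_sd, seed = 400 * seed + i)
  write_correlogram_csv(bare, file.path(out, sprintf("corr_bare_%02d.csv", i)))
  write_correlogram_csv(func, file.path(out, sprintf("corr_func_%02d.csv", i)))
}

## titration of 100-nm gold toward the equilibrium density 0.5 PEG/nm2
gold <- list(core_diameter_nm = 100, particle_concentration_per_uL = 5.6e6,
             volume_uL = 20)
n_particles <- gold$particle_concentration_per_uL * gold$volume_uL
cap <- cfg$chemistry$equilibrium_density_per_nm2 * n_particles * pi * 100^2
ser <- gen_titration(seq(cap / 10, 2 * cap, length.out = 25), cap, gold)
write.csv(ser, file.path(out, "titration.csv"), row.names = FALSE)

## polyplex cores at the two conjugation degrees (shared oligo/PEI amounts)
f_dna <- dna_mass_fraction(cfg$chemistry$np_ratio)
core_mass_ug <- 10 / f_dna
vtot <- core_mass_ug * 1e-6 / (cfg$chemistry$core_density_ug_per_uL * 1e-24)
amines <- (core_mass_ug - 10) * 1e-6 / 43.1 * 6.02214076e23
for (conj in c(7, 10)) {
  pp <- gen_polyplex_cores(formulation(conjugation_pct = conj, pei_pp_ratio = 50),
                           model = list(equilibrium_density_per_nm2 = 0.5,
                                        total_core_volume_nm3 = vtot,
                                        total_amine_count = amines),
                           n = 2000, seed = 500 * seed + conj)
  pp$label <- sprintf("polyplex_conj%d", conj)
  write_populations_csv(pp, file.path(out, sprintf("polyplex_conj%02d.csv", conj)))
}

cat("wrote synthetic study inputs to", out, "\n")
cat(sprintf("  %d gold populations, 4 topographs, %d correlograms, 1 titration, 2 polyplex populations\n",
            length(pops), 2 * length(pops)))
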