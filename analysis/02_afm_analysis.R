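#!/usr/bin/env Rscript
# Stage 2 — AFM image analysis: flatten each topograph (particles masked out
# of the background fit), detect and measure particles, derive
# equivalent-sphere diameters and the shape correction factor, and fit a
# log-normal size distribution to the corrected diameters.

suppressMessages(library(nanoshell))
fix <- "results/fixtures"
out <- "results"
cfg <- default_config(1)

paths <- list.files(fix, pattern = "^topograph_\\d+\\.txt$", full.names = TRUE)
stopifnot(length(paths) > 0)

meas <- do.call(rbind, lapply(paths, function(p) {
  topo <- read_topograph(p)
  m <- measure_topograph(topo, min_height_nm = 5 * cfg$afm$noise_sd_nm * 3.3,
                         min_area_px = cfg$afm$min_area_px,
                         max_eccentricity = cfg$afm$max_eccentricity)
  m$image <- basename(p)
  m
}))
write.csv(meas, file.path(out, "measurements.csv"), row.names = FALSE)

ok <- meas[!meas$excluded, ]
cat(sprintf("measured %d particles (%d excluded: %s)\n", nrow(ok),
            sum(meas$excluded),
            paste(unique(meas$reason[meas$excluded]), collapse = ", ")))

f <- shape_correction_factor(meas)
cat(sprintf("shape correction factor f = %.3f (MAD %.3f, n = %d)\n",
            f$f, f$mad, f$n))

fit <- fit_lognormal(ok$d_eq_nm)
fits <- data.frame(label = "50 nm", median_nm = fit$median_nm,
                   sigma_log = fit$sigma_log, mode_nm = fit$mode_nm, n = fit$n)
write.csv(fits, file.path(out, "fits.csv"), row.names = FALSE)
cat(sprintf("log-normal fit: median %.2f nm, sigma_log %.3f, mode %.2f nm\n",
            fit$median_nm, fit$sigma_log, fit$mode_nm))
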