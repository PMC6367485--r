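#!/usr/bin/env Rscript
# Stage 4 — core-shell inference: join the AFM modal core diameters with the
# DLS z-averages, screen for curvature (< 50 nm) and polydispersity, and
# estimate the shell thickness from the shift between the functionalized and
# bare trendlines, with the k = 2 uncertainty budget.

suppressMessages(library(nanoshell))
fix <- "results/fixtures"
out <- "results"
cfg <- default_config(1)

# AFM side: modal diameter of each generated core population (the per-member
# imaging campaign is summarized by the log-normal fit of each population)
pops <- read_populations_csv(file.path(fix, "populations.csv"))
afm <- do.call(rbind, lapply(names(pops), function(lb) {
  fit <- fit_lognormal(pops[[lb]]$diameters)
  data.frame(label = lb, d_afm_nm = fit$mode_nm, sigma_log_afm = fit$sigma_log)
}))

bare <- read.csv(file.path(out, "dls_bare.csv"))
func <- read.csv(file.path(out, "dls_func.csv"))

screen <- function(dls_tab) {
  pair <- build_series_pair(afm, dls_tab[, c("label", "d_dls_nm")])
  screen_rows(pair, cfg$inference$min_core_nm, cfg$inference$max_sigma_log)
}
names(bare)[names(bare) == "z_average_nm"] <- "d_dls_nm"
names(func)[names(func) == "z_average_nm"] <- "d_dls_nm"
pair_bare <- screen(bare)
pair_func <- screen(func)

est_bare <- estimate_shell_thickness(pair_bare)
est_func <- estimate_shell_thickness(pair_func)
L <- est_func$thickness_nm - est_bare$thickness_nm
se <- sqrt(est_func$se_nm^2 + est_bare$se_nm^2)

budget <- combine_uncertainty(c(afm = cfg$inference$afm_u_pct / cfg$inference$k,
                                dls = cfg$inference$dls_u_pct / cfg$inference$k),
                              k = cfg$inference$k)

write.csv(data.frame(thickness_nm = L, se_nm = se, n_used = est_func$n_used),
          file.path(out, "shell_estimate.csv"), row.names = FALSE)
write.csv(rbind(cbind(series = "bare", est_bare$excluded),
                cbind(series = "functionalized", est_func$excluded)),
          file.path(out, "exclusions.csv"), row.names = FALSE)

cat(sprintf("shell thickness L = %.2f nm (se %.2f nm, %d members used)\n",
            L, se, est_func$n_used))
cat(sprintf("reference (bare) trendline offset: %.2f nm\n",
            2 * est_bare$thickness_nm))
cat(sprintf("uncertainty budget: u_c = %.2f%%, U(k=%d) = %.2f%% (%s)\n",
            budget$combined_pct, budget$coverage_k, budget$expanded_pct,
            budget$confidence_label))
cat(sprintf("excluded members: %s\n",
            paste(unique(est_func$excluded$label), collapse = ", ")))
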