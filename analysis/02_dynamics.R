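#!/usr/bin/env Rscript
# Locus dynamics: time- and ensemble-averaged MSDs, anomalous-diffusion
# power-law fits, short-time effective diffusion constants and gyration
# radii per locus. Requires analysis/01_simulate_dataset.R to have run.
#
# Writes: results/dynamics/{eamsd.csv, per_trajectory.csv, locus_summary.csv}

suppressPackageStartupMessages(library(chromotrace))

ens <- read_trajectories("results/data/trajectories.csv")
out_dir <- "results/dynamics"
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

per <- do.call(rbind, lapply(ens, function(tr) {
  fit <- fit_msd_power_law(compute_tamsd(tr))
  data.frame(cell_id = tr$cell_id, locus_id = tr$locus_id,
             D_app = fit$D_app, beta = fit$beta,
             D_eff = estimate_deff(tr)$D_eff,
             R_g_um = compute_rg(tr)$R_g)
}))
write.csv(per, file.path(out_dir, "per_trajectory.csv"), row.names = FALSE)

groups <- split_ensemble(ens, "locus_id")
eamsd <- do.call(rbind, lapply(names(groups), function(g) {
  curve <- compute_eamsd(groups[[g]], 30)
  data.frame(locus_id = g, lag_s = curve$lag_s, msd_um2 = curve$msd_um2,
             n = curve$n_pairs)
}))
write.csv(eamsd, file.path(out_dir, "eamsd.csv"), row.names = FALSE)

summ <- do.call(rbind, lapply(split(per, per$locus_id), function(d) {
  data.frame(locus_id = d$locus_id[1], n = nrow(d),
             mean_beta = mean(d$beta),
             mean_D_eff = mean(d$D_eff),
             mean_R_g_um = mean(d$R_g_um), sd_R_g_um = sd(d$R_g_um))
}))
write.csv(summ, file.path(out_dir, "locus_summary.csv"), row.names = FALSE)

cat("Per-locus dynamics (ensemble means):\n")
print(summ, row.names = FALSE, digits = 3)
cat("\nNote: measured D_eff and the power-law fits include the ~50 nm\n")
cat("localization floor. For these strongly confined loci a free-exponent\n")
cat("offset fit is degenerate (a small beta mimics the flat noise floor), so\n")
cat("the noise level is estimated from a short-lag linear fit (slope 4D,\n")
cat("intercept 4 sigma^2); confinement curvature biases it slightly high:\n")
m <- compute_eamsd(ens, 30)
co <- coef(lm(m$msd_um2[1:3] ~ m$lag_s[1:3]))
cat(sprintf("  sigma_loc = %.4f um (generator value 0.05)\n",
            sqrt(max(co[[1]], 0) / 4)))
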