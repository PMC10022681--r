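#!/usr/bin/env Rscript
# Chromosome organization: locus-pair distances and the compaction exponent,
# cell-to-cell versus temporal variation, and nuclear radiality with its
# mobility correlation.
#
# The compaction analysis runs on the dedicated locus-pair generator (the
# trajectory dataset of analysis/01 places loci independently in each
# nucleus, so cross-locus distances there carry nuclear geometry, not
# chromosome compaction). Pair genomic separations match the five spans of
# a chromosome arm panel: 1.93, 2.69, 4.62, 25.82 and 29.05 Mb.
#
# Writes: results/organization/{compaction.csv, variation.csv,
#         radiality.csv, nrd_cdf.csv}

suppressPackageStartupMessages(library(chromotrace))

ens <- read_trajectories("results/data/trajectories.csv")
nuclei <- read_nucleus_geometry(json_file = "results/data/nuclei.json")
out_dir <- "results/organization"
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

# --- locus-pair distances and compaction ------------------------------------
s_mb <- c("LH/LA" = 1.93, "LA/T2" = 2.69, "LH/T2" = 4.62,
          "LE/T2" = 25.82, "PR2/T2" = 29.05)
series <- generate_pair_distances(delta = 0.2, prefactor = 0.4,
                                  genomic_distances = s_mb,
                                  cell_sd = 0.1, temporal_sd = 0.05,
                                  n_cells = 40, n_frames = 30,
                                  seed = 190304)
lab <- vapply(series, `[[`, "", "pair")
comp <- do.call(rbind, lapply(split(series, lab), function(g) {
  mp <- mean_pair_distance(g, n_frames_avg = 30)
  data.frame(pair = g[[1]]$pair, s_mb = g[[1]]$genomic_distance,
             mean_r_um = mp$mean_r, sd_r_um = mp$sd_r, n_cells = mp$n_cells)
}))
comp <- comp[order(comp$s_mb), ]
fit <- fit_compaction(comp$s_mb, comp$mean_r_um,
                      spans = c("5Mb" = 5, "30Mb" = 31))
write.csv(cbind(comp, delta_global = fit$delta),
          file.path(out_dir, "compaction.csv"), row.names = FALSE)
cat("Locus-pair compaction (generator delta = 0.20, prefactor = 0.40):\n")
print(comp, row.names = FALSE, digits = 3)
cat(sprintf("recovered delta = %.3f (prefactor %.3f); nested: delta_5Mb = %.3f, delta_30Mb = %.3f\n",
            fit$delta, fit$prefactor, fit$span_fits[["5Mb"]]$delta,
            fit$span_fits[["30Mb"]]$delta))

# --- variation decomposition ------------------------------------------------
var_tab <- do.call(rbind, lapply(split(series, lab), function(g) {
  dv <- decompose_variation(g)
  data.frame(pair = g[[1]]$pair, cell_sd_um = dv$cell_sd,
             mean_temporal_dev_um = dv$mean_temporal_dev,
             implied_temporal_sd_um = dv$implied_temporal_sd)
}))
write.csv(var_tab, file.path(out_dir, "variation.csv"), row.names = FALSE)
cat("\nCell-to-cell vs temporal variation (generator: 0.10 / 0.05 um):\n")
print(var_tab, row.names = FALSE, digits = 3)

# --- per-frame distance series (mechanics of the pair pipeline) -------------
# within one cell of the trajectory dataset, the per-frame distance between
# two loci is the raw material of the analysis above
cell1 <- split_ensemble(ens, "cell_id")[[1L]]
ids <- vapply(cell1, `[[`, "", "locus_id")
demo_pair <- compute_pair_distance_series(cell1[[match("LH", ids)]],
                                          cell1[[match("LA", ids)]],
                                          genomic_distance = 1.93)
cat(sprintf("\nExample per-frame pair series (%s, cell %s): mean R = %.2f um over %d frames\n",
            demo_pair$pair, demo_pair$cell_id, mean(demo_pair$distances),
            length(demo_pair$distances)))

# --- nuclear radiality ------------------------------------------------------
rad <- do.call(rbind, lapply(ens, function(tr) {
  rec <- compute_nrd(colMeans(tr$positions), nuclei[[tr$cell_id]])
  data.frame(cell_id = tr$cell_id, locus_id = tr$locus_id, nrd = rec$nrd,
             D_eff = estimate_deff(tr)$D_eff)
}))
write.csv(rad, file.path(out_dir, "radiality.csv"), row.names = FALSE)

cdf_tab <- do.call(rbind, lapply(split(rad, rad$locus_id), function(d) {
  nd <- nrd_distribution(d$nrd)
  grid <- seq(0, 1, by = 0.05)
  data.frame(locus_id = d$locus_id[1], nrd = grid, cdf = nd$cdf(grid))
}))
write.csv(cdf_tab, file.path(out_dir, "nrd_cdf.csv"), row.names = FALSE)

cat("\nNRD medians and mobility-position correlation by locus:\n")
for (d in split(rad, rad$locus_id)) {
  cr <- correlate_mobility_position(d$nrd, d$D_eff)
  cat(sprintf("  %-4s median NRD = %.2f, r(NRD, D_eff) = %+.2f (%s)\n",
              d$locus_id[1], median(d$nrd), cr$r, cr$class))
}
cat("\n(With 25 cells per locus and mobility independent of position by\n")
cat("construction, correlations of |r| ~ 0.4 arise from sampling noise;\n")
cat("the classification thresholds are descriptive, not significance tests.)\n")
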