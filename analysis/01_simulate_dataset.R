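#!/usr/bin/env Rscript
# Build the synthetic single-chromosome tracking dataset used by the rest of
# the analysis: six loci spanning a chromosome arm (two pericentromeric, three
# interior, one near-telomeric), each imaged 120 frames at 0.667 s in ~25
# cells, with 50 nm localization noise. Confinement strengths are chosen so
# gyration radii span ~0.09-0.15 um and short-time diffusion constants
# ~0.0025-0.0042 um^2/s, the scale typical of interphase chromatin loci.
# Each cell also gets an elliptical nucleus with the locus placed at its
# locus-specific preferred radial fraction.
#
# Writes: results/data/trajectories.csv, results/data/nuclei.json

suppressPackageStartupMessages(library(chromotrace))
set.seed(190301)

out_dir <- "results/data"
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

# locus panel: confinement k (k_BT/um^2), short-time D (um^2/s), preferred
# radial fraction and genomic coordinate (Mb along the arm)
panel <- data.frame(
  locus_id = c("PR1", "PR2", "LE", "LH", "LA", "T2"),
  k        = c(260,  120,   85,   88,   92,   87),
  D        = c(0.0025, 0.0039, 0.0042, 0.0035, 0.0033, 0.0033),
  nrd      = c(0.5,  0.55, 0.75, 0.75, 0.78, 0.85),
  c_mb     = c(0,    1.0,  4.2,  27.1, 29.0, 30.0)
)
n_cells <- 25L
sigma_loc <- 0.05

trajs <- list()
nuclei <- list()
for (cell_i in seq_len(n_cells)) {
  cell <- sprintf("cell%03d", cell_i)
  a <- runif(1, 7, 9); b <- runif(1, 5.5, 7)
  angles <- runif(nrow(panel), 0, 2 * pi)
  nuc <- simulate_nucleus(cell, center = c(0, 0), a = a, b = b,
                          loci = data.frame(locus_id = panel$locus_id,
                                            nrd = panel$nrd, angle = angles))
  nuclei[[cell]] <- list(cell_id = cell, centroid = c(0, 0),
                         ellipse = list(cx = 0, cy = 0, a_um = a, b_um = b,
                                        theta_rad = 0))
  for (j in seq_len(nrow(panel))) {
    tr <- simulate_ou(panel$k[j], panel$D[j],
                      center = unlist(nuc$loci[j, c("x_um", "y_um")]),
                      n_frames = 120, frame_interval = 2 / 3)[[1L]]
    trajs[[length(trajs) + 1L]] <- locus_trajectory(
      cell, panel$locus_id[j], times = tr$times,
      x = tr$positions[, 1L], y = tr$positions[, 2L], condition = "async",
      meta = list(genomic_coord_mb = panel$c_mb[j]))
  }
}
ens <- add_localization_noise(trajectory_ensemble(trajs), sigma_loc)

write_trajectories(ens, file.path(out_dir, "trajectories.csv"))
cat(jsonlite::toJSON(unname(nuclei), auto_unbox = TRUE, digits = NA),
    file = file.path(out_dir, "nuclei.json"))
# locus panel doubles as ground truth for the later drivers
write.csv(panel, file.path(out_dir, "panel_ground_truth.csv"),
          row.names = FALSE)

cat(sprintf("wrote %d trajectories (%d loci x %d cells) and %d nuclei to %s\n",
            length(ens), nrow(panel), n_cells, length(nuclei), out_dir))
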