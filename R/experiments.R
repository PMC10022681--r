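# Self-contained validation experiments: simulate under known ground truth,
# run the estimators, and return the recovered quantities. Used by the
# analysis drivers, the test suite and the acceptance script.

#' Spring-constant versus territory sweep on confined beads
#'
#' Simulates harmonically confined loci over a range of spring constants,
#' estimates `k_eff` (step-size regression) and `R_g^2` per trajectory, and
#' fits the power law `<k_eff> = a <R_g^2>^-b` across the sweep. The
#' stationary identity `k Var = k_B T` per axis predicts `a = 2`, `b = 1`.
#' The frame interval is set per spring constant as
#' `dt_over_tau / (D * k)`, keeping the sampling in the short-time regime
#' throughout the sweep.
#'
#' @param k_values Spring constants to sweep, k_B*T um^-2.
#' @param D Diffusion constant, um^2/s.
#' @param dt_over_tau Frame interval over relaxation time (<= 0.05 keeps the
#'   first-order slope mapping accurate to a few percent).
#' @param n_frames,n_traj Frames per trajectory and trajectories per spring
#'   constant.
#' @param seed Optional integer seed.
#' @return A list: `points` (data.frame `k_true`, `mean_k_eff`,
#'   `mean_rg2_um2`) and `fit` (a `spring_territory_fit` with `a`, `b`).
#' @export
spring_territory_sweep <- function(k_values = c(25, 50, 100, 200, 400),
                                   D = 0.0035, dt_over_tau = 0.02,
                                   n_frames = 4000L, n_traj = 100L,
                                   seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  rows <- lapply(k_values, function(k) {
    dt <- dt_over_tau / (D * k)
    ens <- simulate_ou(k, D, n_trajectories = n_traj, n_frames = n_frames,
                       frame_interval = dt)
    keff <- vapply(ens, function(tr) estimate_keff(tr)$k_eff, numeric(1))
    rg2 <- vapply(ens, function(tr) compute_rg(tr)$R_g^2, numeric(1))
    data.frame(k_true = k, mean_k_eff = mean(keff),
               mean_rg2_um2 = mean(rg2))
  })
  points <- do.call(rbind, rows)
  list(points = points,
       fit = fit_keff_vs_territory(points$mean_k_eff, points$mean_rg2_um2))
}

#' Inter-bead distance scaling of a free Rouse chain
#'
#' Simulates free chains, measures the mean spatial distance between bead
#' pairs as a function of bond separation, and fits the power-law exponent.
#' The Gaussian-chain prediction is an exponent of 0.5.
#'
#' @param n_beads Beads per chain.
#' @param neighbor_spring Bond spring constant, k_B*T um^-2.
#' @param bead_diffusion Bead diffusion constant, um^2/s.
#' @param n_chains Independent chains.
#' @param n_frames Recorded frames per chain (spaced one slowest relaxation
#'   time apart so frames are nearly independent).
#' @param max_separation Largest bond separation analyzed (default half the
#'   chain, avoiding end effects).
#' @param seed Optional integer seed.
#' @return A list: `points` (data.frame `separation_bonds`, `mean_r_um`),
#'   `exponent` (fitted scaling exponent), `fit` (the `compaction_fit`).
#' @export
rouse_free_chain_scaling <- function(n_beads = 32L, neighbor_spring = 10,
                                     bead_diffusion = 0.01, n_chains = 16L,
                                     n_frames = 5L, max_separation = NULL,
                                     seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  spec <- rouse_chain_spec(n_beads, neighbor_spring, bead_diffusion,
                           labeled_beads = seq_len(n_beads))
  tau <- rouse_slowest_time(spec)
  ens <- simulate_rouse_chain(spec, n_trajectories = n_chains,
                              n_frames = n_frames, frame_interval = tau)
  if (is.null(max_separation)) max_separation <- n_beads %/% 2L
  # regroup positions: chains x frames x beads
  by_chain <- split_ensemble(ens, "cell_id")
  sep <- seq_len(max_separation)
  sums <- numeric(max_separation)
  counts <- integer(max_separation)
  for (chain in by_chain) {
    beads <- vapply(chain, function(tr) tr$meta$bead, 0L)
    ord <- order(beads)
    xs <- vapply(chain[ord], function(tr) tr$positions[, 1L],
                 numeric(n_frames))
    ys <- vapply(chain[ord], function(tr) tr$positions[, 2L],
                 numeric(n_frames))
    xs <- matrix(xs, nrow = n_frames)
    ys <- matrix(ys, nrow = n_frames)
    for (s in sep) {
      dx <- xs[, (1L + s):n_beads, drop = FALSE] -
        xs[, 1L:(n_beads - s), drop = FALSE]
      dy <- ys[, (1L + s):n_beads, drop = FALSE] -
        ys[, 1L:(n_beads - s), drop = FALSE]
      r <- sqrt(dx * dx + dy * dy)
      sums[s] <- sums[s] + sum(r)
      counts[s] <- counts[s] + length(r)
    }
  }
  points <- data.frame(separation_bonds = sep, mean_r_um = sums / counts)
  fit <- fit_compaction(points$separation_bonds, points$mean_r_um)
  list(points = points, exponent = fit$delta, fit = fit)
}

#' Stationary radii of a tethered single bead (Rouse integrator) and the
#' matched Ornstein-Uhlenbeck reference
#'
#' A one-bead chain with a tether is exactly an OU process, so the
#' Euler-Maruyama integrator can be checked in distribution against the
#' exact OU sampler. Frames are spaced several relaxation times apart so
#' the returned radii are effectively independent samples.
#'
#' @param k_t Tether spring constant, k_B*T um^-2.
#' @param D Bead diffusion constant, um^2/s.
#' @param n_chains,n_frames Chains and frames per chain (total samples =
#'   product).
#' @param spacing_tau Frame spacing in units of the relaxation time.
#' @param seed Optional integer seed.
#' @return A list with numeric vectors `rouse_radii` and `ou_radii` (um).
#' @export
tethered_bead_vs_ou <- function(k_t = 100, D = 0.0035, n_chains = 200L,
                                n_frames = 50L, spacing_tau = 3,
                                seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  tau <- 1 / (D * k_t)
  dt <- spacing_tau * tau
  spec <- rouse_chain_spec(1L, neighbor_spring = 0, bead_diffusion = D,
                           tether = list(bead = 1L, anchor = c(0, 0),
                                         k_t = k_t))
  rouse <- simulate_rouse_chain(spec, n_trajectories = n_chains,
                                n_frames = n_frames, frame_interval = dt)
  ou <- simulate_ou(k_t, D, n_trajectories = n_chains, n_frames = n_frames,
                    frame_interval = dt)
  radii <- function(ens) {
    unlist(lapply(ens, function(tr) sqrt(rowSums(tr$positions^2))))
  }
  list(rouse_radii = radii(rouse), ou_radii = radii(ou))
}
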