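#' Specify a Rouse chain
#'
#' Beads joined by harmonic nearest-neighbor springs with independent
#' thermal noise; optionally one bead is tethered to a fixed lab-frame
#' anchor (modelling attachment to a nuclear landmark). The chain stiffness
#' between two beads separated by `n` bonds is `neighbor_spring / n`, so in
#' genomic units the chain spring constant per genomic distance is
#' `K_R = neighbor_spring * genomic_spacing` (k_B*T um^-2 Mb).
#'
#' @param n_beads Number of beads (>= 1).
#' @param neighbor_spring Nearest-neighbor spring constant, k_B*T um^-2.
#' @param bead_diffusion Free-bead diffusion constant, um^2/s.
#' @param tether Optional `list(bead =, anchor =, k_t =)`: 1-based bead
#'   index, length-2 anchor point (um) and tether spring constant
#'   (k_B*T um^-2).
#' @param labeled_beads 1-based indices of the beads whose positions are
#'   recorded (one output trajectory per labeled bead per replicate).
#' @param genomic_spacing Genomic distance per bond, Mb.
#' @return Object of class `rouse_chain_spec`.
#' @export
rouse_chain_spec <- function(n_beads, neighbor_spring, bead_diffusion,
                             tether = NULL, labeled_beads = 1L,
                             genomic_spacing = 0.1) {
  stopifnot(n_beads >= 1L, neighbor_spring >= 0, bead_diffusion > 0,
            genomic_spacing > 0)
  labeled_beads <- as.integer(labeled_beads)
  if (any(labeled_beads < 1L | labeled_beads > n_beads)) {
    stop("labeled_beads out of range", call. = FALSE)
  }
  if (!is.null(tether)) {
    stopifnot(is.list(tether),
              all(c("bead", "anchor", "k_t") %in% names(tether)))
    if (tether$bead < 1L || tether$bead > n_beads || tether$k_t < 0) {
      stop("invalid tether specification", call. = FALSE)
    }
  }
  structure(list(n_beads = as.integer(n_beads),
                 neighbor_spring = neighbor_spring,
                 bead_diffusion = bead_diffusion,
                 tether = tether,
                 labeled_beads = labeled_beads,
                 genomic_spacing = genomic_spacing),
            class = "rouse_chain_spec")
}

# Slowest relaxation time of the chain/tether system (used to size burn-in
# and to choose decorrelated sampling intervals). Computed exactly from the
# smallest positive eigenvalue of the harmonic stiffness matrix; for a free
# chain the zero (center-of-mass) mode is excluded, recovering the discrete
# Rouse spectrum 4 k sin^2(pi/(2N)).
rouse_slowest_time <- function(spec) {
  n <- spec$n_beads
  k_s <- spec$neighbor_spring
  k_t <- if (is.null(spec$tether)) 0 else spec$tether$k_t
  if (n == 1L) {
    return(if (k_t > 0) 1 / (spec$bead_diffusion * k_t) else 0)
  }
  K <- diag(0, n)
  for (j in seq_len(n - 1L)) {
    K[j, j] <- K[j, j] + k_s
    K[j + 1L, j + 1L] <- K[j + 1L, j + 1L] + k_s
    K[j, j + 1L] <- K[j, j + 1L] - k_s
    K[j + 1L, j] <- K[j + 1L, j] - k_s
  }
  if (k_t > 0) {
    tb <- spec$tether$bead
    K[tb, tb] <- K[tb, tb] + k_t
  }
  ev <- eigen(K, symmetric = TRUE, only.values = TRUE)$values
  ev <- ev[ev > max(ev) * 1e-12]
  if (!length(ev)) return(0)
  1 / (spec$bead_diffusion * min(ev))
}

#' Simulate Rouse-chain bead trajectories
#'
#' Overdamped Euler-Maruyama Brownian dynamics with an internal substep at
#' most `0.01 / (bead_diffusion * k_max)` seconds, where `k_max` is the
#' stiffest local force constant (`2 * neighbor_spring` plus the tether, if
#' any). Chains are initialized from the free-chain equilibrium bond
#' distribution and additionally equilibrated for ten slowest-mode
#' relaxation times before recording. Labeled-bead positions are sampled
#' every `frame_interval`.
#'
#' Each output trajectory carries `meta$genomic_coord_mb`
#' (`(bead - 1) * genomic_spacing`) and `meta$bead`, so tethering analyses
#' can recover genomic positions.
#'
#' @param spec A [rouse_chain_spec()].
#' @param n_trajectories Independent chain replicates.
#' @param n_frames Recorded frames per trajectory.
#' @param frame_interval Seconds between recorded frames.
#' @param seed Optional integer seed.
#' @param burn_in_factor Burn-in length in units of the slowest relaxation
#'   time (default 10).
#' @return A [trajectory_ensemble()] with one trajectory per
#'   (replicate, labeled bead); `locus_id` is `"bead<j>"`.
#' @export
simulate_rouse_chain <- function(spec, n_trajectories = 1L,
                                 n_frames = default_frames,
                                 frame_interval = default_dt, seed = NULL,
                                 burn_in_factor = 10) {
  stopifnot(inherits(spec, "rouse_chain_spec"), n_frames >= 2L,
            n_trajectories >= 1L, frame_interval > 0)
  if (!is.null(seed)) set.seed(seed)
  D <- spec$bead_diffusion
  k_t <- if (is.null(spec$tether)) 0 else spec$tether$k_t
  anchor <- if (is.null(spec$tether)) c(0, 0) else as.numeric(spec$tether$anchor)
  k_max <- 2 * spec$neighbor_spring + k_t
  h_bound <- if (k_max > 0) 0.01 / (D * k_max) else frame_interval
  sub_per_frame <- max(1L, as.integer(ceiling(frame_interval / h_bound)))
  h <- frame_interval / sub_per_frame
  if (D * k_max * h >= 0.5) {
    stop("unstable Rouse substep; reduce frame_interval or spring constants",
         call. = FALSE)
  }
  burn_time <- burn_in_factor * rouse_slowest_time(spec)

  # equilibrium-ish initial state: chains rooted at the anchor with
  # free-chain Gaussian bonds
  nb <- spec$n_beads
  bond_sd <- if (spec$neighbor_spring > 0) sqrt(1 / spec$neighbor_spring) else 0
  state <- matrix(0, n_trajectories * nb, 2L)
  for (tr in seq_len(n_trajectories)) {
    if (nb == 1L) {
      pos <- matrix(0, 1L, 2L)
    } else {
      bonds <- matrix(stats::rnorm(2L * (nb - 1L), sd = bond_sd), ncol = 2L)
      pos <- rbind(c(0, 0), apply(bonds, 2L, function(v) cumsum(v)))
      if (nb == 2L) pos <- rbind(c(0, 0), as.numeric(bonds))
    }
    # shift so the tethered bead starts at its anchor
    ref <- if (k_t > 0) spec$tether$bead else 1L
    pos <- sweep(pos, 2L, pos[ref, ] - anchor)
    state[(tr - 1L) * nb + seq_len(nb), ] <- pos
  }

  raw <- rouse_bd_cpp(state, n_trajectories, nb, spec$neighbor_spring, D, h,
                      if (k_t > 0) spec$tether$bead - 1L else -1L,
                      anchor, k_t, burn_time, n_frames, sub_per_frame)
  times <- (seq_len(n_frames) - 1L) * frame_interval
  trajs <- list()
  for (tr in seq_len(n_trajectories)) {
    for (j in spec$labeled_beads) {
      row <- (tr - 1L) * nb + j
      trajs[[length(trajs) + 1L]] <- locus_trajectory(
        cell_id = sprintf("chain%04d", tr),
        locus_id = sprintf("bead%d", j),
        times = times, x = raw[, row, 1L], y = raw[, row, 2L],
        meta = list(bead = j,
                    genomic_coord_mb = (j - 1L) * spec$genomic_spacing))
    }
  }
  trajectory_ensemble(trajs)
}
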