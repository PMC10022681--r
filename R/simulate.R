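# Synthetic-data generators. These define the study conditions under which
# every estimator in the package is validated: confined subdiffusive loci
# imaged for 120 frames over 80 s (frame interval 0.667 s), short-time
# diffusion constants of a few 1e-3 um^2/s, ~50 nm localization noise.
# Energies are expressed in units of k_B*T, so spring constants are
# k_B*T um^-2 and the overdamped mobility equals the diffusion constant.
#
# All generators consume R's global RNG; passing `seed` calls set.seed()
# first, making output bit-reproducible. Each generator draws its variates
# in a fixed documented order (trajectory-major, frame-minor, x before y).

default_frames <- 120L
default_dt <- 80 / 120  # seconds per frame, as in an 80 s / 120 frame movie

make_sim_ensemble <- function(xs, ys, frame_interval, locus_id, condition,
                              cell_prefix = "sim", meta_fn = NULL) {
  n_traj <- ncol(xs)
  times <- (seq_len(nrow(xs)) - 1L) * frame_interval
  trajs <- lapply(seq_len(n_traj), function(i) {
    locus_trajectory(sprintf("%s%04d", cell_prefix, i), locus_id,
                     times = times, x = xs[, i], y = ys[, i],
                     condition = condition,
                     meta = if (is.null(meta_fn)) list() else meta_fn(i))
  })
  trajectory_ensemble(trajs)
}

#' Simulate free 2D Brownian trajectories
#'
#' Gaussian increments with per-axis variance `2 * D * frame_interval` per
#' step; the free-diffusion limit of the confined Langevin model and the
#' oracle for the diffusion estimators.
#'
#' @param D Diffusion constant, um^2/s (`D = 0` gives constant trajectories).
#' @param n_trajectories Number of independent trajectories.
#' @param n_frames Frames per trajectory (>= 2).
#' @param frame_interval Seconds between frames.
#' @param origin Common starting point (um).
#' @param seed Optional integer seed for bit-reproducibility.
#' @param locus_id,condition Labels attached to the output.
#' @return A [trajectory_ensemble()].
#' @export
simulate_brownian <- function(D, n_trajectories = 1L,
                              n_frames = default_frames,
                              frame_interval = default_dt,
                              origin = c(0, 0), seed = NULL,
                              locus_id = "SIM", condition = NA_character_) {
  stopifnot(D >= 0, n_frames >= 2L, n_trajectories >= 1L, frame_interval > 0)
  if (!is.null(seed)) set.seed(seed)
  sd_step <- sqrt(2 * D * frame_interval)
  m <- n_frames - 1L
  steps <- array(stats::rnorm(m * n_trajectories * 2L, sd = sd_step),
                 dim = c(m, n_trajectories, 2L))
  xs <- apply(steps[, , 1L, drop = FALSE], 2L, cumsum)
  ys <- apply(steps[, , 2L, drop = FALSE], 2L, cumsum)
  xs <- rbind(0, matrix(xs, nrow = m)) + origin[1L]
  ys <- rbind(0, matrix(ys, nrow = m)) + origin[2L]
  make_sim_ensemble(xs, ys, frame_interval, locus_id, condition)
}

#' Simulate a harmonically confined locus (Ornstein-Uhlenbeck)
#'
#' Exact discrete OU transitions per axis: positions decay towards `center`
#' with relaxation time `tau = 1 / (D * k)` (k_B*T = 1) and stationary
#' per-axis variance `1 / k`. The initial point is drawn from the stationary
#' law, so every frame is a stationary sample. Because the exact transition
#' kernel is used there is no integration error; this generator is the
#' analytic oracle for the spring-constant estimator.
#'
#' @param k Effective spring constant, k_B*T um^-2 (`k = 0` falls back to
#'   [simulate_brownian()]).
#' @param D Diffusion constant, um^2/s.
#' @param center Confinement center (um).
#' @inheritParams simulate_brownian
#' @return A [trajectory_ensemble()].
#' @export
simulate_ou <- function(k, D, center = c(0, 0), n_trajectories = 1L,
                        n_frames = default_frames,
                        frame_interval = default_dt, seed = NULL,
                        locus_id = "SIM", condition = NA_character_) {
  stopifnot(k >= 0, D > 0, n_frames >= 2L)
  if (k == 0) {
    return(simulate_brownian(D, n_trajectories, n_frames, frame_interval,
                             origin = center, seed = seed,
                             locus_id = locus_id, condition = condition))
  }
  if (!is.null(seed)) set.seed(seed)
  rho <- exp(-D * k * frame_interval)
  sd_stat <- sqrt(1 / k)
  sd_cond <- sd_stat * sqrt(1 - rho^2)
  xs <- matrix(0, n_frames, n_trajectories)
  ys <- matrix(0, n_frames, n_trajectories)
  xs[1L, ] <- stats::rnorm(n_trajectories, sd = sd_stat)
  ys[1L, ] <- stats::rnorm(n_trajectories, sd = sd_stat)
  for (t in seq_len(n_frames - 1L)) {
    xs[t + 1L, ] <- rho * xs[t, ] + stats::rnorm(n_trajectories, sd = sd_cond)
    ys[t + 1L, ] <- rho * ys[t, ] + stats::rnorm(n_trajectories, sd = sd_cond)
  }
  make_sim_ensemble(xs + center[1L], ys + center[2L], frame_interval,
                    locus_id, condition)
}

# Exact covariance of fractional Gaussian increments for one axis.
fgn_covariance <- function(m, beta, sigma2) {
  h <- 0:(m - 1L)
  g <- sigma2 / 2 * (abs(h + 1)^beta - 2 * abs(h)^beta + abs(h - 1)^beta)
  stats::toeplitz(g)
}

#' Simulate subdiffusive trajectories (fractional Brownian motion)
#'
#' Per-axis fractional Gaussian increments drawn from their exact covariance
#' (Cholesky factorization of the increment covariance matrix, Hurst index
#' `beta / 2`), scaled so the ensemble MSD obeys
#' `MSD(t) = 4 * D_app * t^beta`. `beta = 1` is statistically identical to
#' [simulate_brownian()] with `D = D_app`. Genomic loci typically show
#' `beta` around 0.35-0.46.
#'
#' @param beta Diffusion exponent in (0, 2).
#' @param D_app Apparent diffusion constant, um^2 s^-beta.
#' @inheritParams simulate_brownian
#' @return A [trajectory_ensemble()].
#' @export
simulate_fbm <- function(beta, D_app, n_trajectories = 1L,
                         n_frames = default_frames,
                         frame_interval = default_dt, seed = NULL,
                         locus_id = "SIM", condition = NA_character_) {
  if (beta <= 0 || beta >= 2) stop("beta must lie in (0, 2)", call. = FALSE)
  stopifnot(D_app > 0, n_frames >= 2L)
  if (!is.null(seed)) set.seed(seed)
  m <- n_frames - 1L
  sigma2 <- 2 * D_app * frame_interval^beta  # per-axis lag-1 increment variance
  L <- t(chol(fgn_covariance(m, beta, sigma2)))
  z <- matrix(stats::rnorm(m * 2L * n_trajectories), nrow = m)
  inc <- L %*% z  # columns: x1, y1, x2, y2, ...
  pos <- rbind(0, apply(inc, 2L, cumsum))
  xs <- pos[, seq(1L, 2L * n_trajectories, by = 2L), drop = FALSE]
  ys <- pos[, seq(2L, 2L * n_trajectories, by = 2L), drop = FALSE]
  make_sim_ensemble(xs, ys, frame_interval, locus_id, condition)
}

#' Add localization noise to an ensemble
#'
#' Adds i.i.d. Gaussian offsets (standard deviation `sigma` per axis) to
#' every position, emulating the camera localization uncertainty of a
#' tracking microscope (about 0.05 um for moving loci). Noise is independent
#' across frames, so it contributes a flat `4 * sigma^2` floor to the MSD.
#'
#' @param ensemble A [trajectory_ensemble()].
#' @param sigma Per-axis localization s.d., um (`0` returns the input).
#' @param seed Optional integer seed.
#' @return A [trajectory_ensemble()].
#' @export
add_localization_noise <- function(ensemble, sigma, seed = NULL) {
  stopifnot(inherits(ensemble, "trajectory_ensemble"), sigma >= 0)
  if (sigma == 0) return(ensemble)
  if (!is.null(seed)) set.seed(seed)
  out <- lapply(ensemble, function(tr) {
    n <- n_frames(tr)
    tr$positions <- tr$positions +
      matrix(stats::rnorm(2L * n, sd = sigma), ncol = 2L)
    colnames(tr$positions) <- c("x_um", "y_um")
    tr
  })
  trajectory_ensemble(out)
}

#' Simulate a nucleus with loci at prescribed radial positions
#'
#' Builds an elliptical nucleus and places loci at given normalized radial
#' distances (NRD, 0 = centroid, 1 = boundary) and polar angles. Placement is
#' exact: [compute_nrd()] on the returned positions reproduces the targets
#' to numerical precision.
#'
#' @param cell_id Cell identifier.
#' @param center Ellipse center = nuclear centroid (um).
#' @param a,b Semi-axes (um).
#' @param theta Ellipse rotation (radians).
#' @param loci A data.frame with columns `locus_id`, `nrd` (in \[0, 1\]) and
#'   `angle` (radians, lab frame).
#' @return A list with the `geometry` ([nucleus_geometry()]) and a `loci`
#'   data.frame (`locus_id`, `x_um`, `y_um`, `nrd`).
#' @export
simulate_nucleus <- function(cell_id, center, a, b, theta = 0, loci) {
  stopifnot(is.data.frame(loci),
            all(c("locus_id", "nrd", "angle") %in% names(loci)))
  if (any(loci$nrd < 0 | loci$nrd > 1)) {
    stop("target NRD values must lie in [0, 1]", call. = FALSE)
  }
  boundary <- ellipse_boundary(center, a, b, theta)
  geom <- nucleus_geometry(cell_id, centroid = center, boundary = boundary)
  pos <- t(vapply(seq_len(nrow(loci)), function(i) {
    u <- c(cos(loci$angle[i]), sin(loci$angle[i]))
    rho <- ray_boundary_distance(boundary, center, u)
    center + loci$nrd[i] * rho * u
  }, numeric(2)))
  list(geometry = geom,
       loci = data.frame(locus_id = loci$locus_id,
                         x_um = pos[, 1L], y_um = pos[, 2L],
                         nrd = loci$nrd, stringsAsFactors = FALSE))
}

#' Generate synthetic locus-pair distance series
#'
#' Emulates the two variation sources seen in locus-pair imaging: the
#' per-cell mean distance follows the compaction power law
#' `prefactor * s^delta` plus a cell-to-cell Gaussian offset
#' (s.d. `cell_sd`, redrawn while non-positive), and frames jitter around
#' the cell mean with s.d. `temporal_sd` (negative draws redrawn, which is
#' negligible at realistic parameters).
#'
#' @param delta Compaction exponent (> 0).
#' @param prefactor Power-law prefactor, um Mb^-delta.
#' @param genomic_distances Named or unnamed numeric vector of genomic
#'   separations s, in Mb; names become pair labels.
#' @param cell_sd Cell-to-cell s.d. of the time-mean distance, um.
#' @param temporal_sd Frame-to-frame s.d. around the cell mean, um.
#' @param n_cells Cells per pair.
#' @param n_frames Frames per cell (default 30, the averaging window).
#' @param seed Optional integer seed.
#' @return A list of [locus_pair_series()] objects.
#' @export
generate_pair_distances <- function(delta, prefactor, genomic_distances,
                                    cell_sd = 0, temporal_sd = 0,
                                    n_cells = 1L, n_frames = 30L,
                                    seed = NULL) {
  stopifnot(delta > 0, prefactor > 0, cell_sd >= 0, temporal_sd >= 0,
            n_cells >= 1L, n_frames >= 1L)
  if (!is.null(seed)) set.seed(seed)
  labels <- names(genomic_distances)
  if (is.null(labels)) labels <- sprintf("pair_s%g", genomic_distances)
  out <- list()
  for (j in seq_along(genomic_distances)) {
    s <- genomic_distances[[j]]
    base <- prefactor * s^delta
    for (cell in seq_len(n_cells)) {
      mu <- base + stats::rnorm(1L, sd = cell_sd)
      while (mu <= 0) mu <- base + stats::rnorm(1L, sd = cell_sd)
      r <- mu + stats::rnorm(n_frames, sd = temporal_sd)
      while (any(bad <- r <= 0)) {
        r[bad] <- mu + stats::rnorm(sum(bad), sd = temporal_sd)
      }
      out[[length(out) + 1L]] <- locus_pair_series(
        cell_id = sprintf("cell%04d", cell), pair = labels[[j]],
        genomic_distance = s, distances = r)
    }
  }
  out
}
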