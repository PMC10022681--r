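# Mean square displacement machinery, anomalous-diffusion power-law fits,
# short-time effective diffusion constants, gyration radii and
# localization-precision utilities.

msd_curve <- function(lag_s, msd, n_pairs, kind, frame_interval) {
  out <- data.frame(lag_s = lag_s, msd_um2 = msd, n_pairs = n_pairs)
  class(out) <- c("msd_curve", "data.frame")
  attr(out, "kind") <- kind
  attr(out, "frame_interval") <- frame_interval
  out
}

#' Time-averaged mean square displacement
#'
#' `MSD(k dt) = mean_m |p((m+k) dt) - p(m dt)|^2` over all overlapping start
#' frames `m`, for lags `k = 1 .. max_lag_k`.
#'
#' @param traj A [locus_trajectory()].
#' @param max_lag_k Largest lag index (default all, `n_frames - 1`).
#' @return An `msd_curve` data.frame with columns `lag_s`, `msd_um2`,
#'   `n_pairs` and attribute `kind = "time"`.
#' @export
compute_tamsd <- function(traj, max_lag_k = NULL) {
  stopifnot(inherits(traj, "locus_trajectory"))
  n <- n_frames(traj)
  if (is.null(max_lag_k)) max_lag_k <- n - 1L
  if (max_lag_k >= n || max_lag_k < 1L) {
    stop(sprintf("max_lag_k must lie in [1, %d]", n - 1L), call. = FALSE)
  }
  p <- traj$positions
  ks <- seq_len(max_lag_k)
  msd <- vapply(ks, function(k) {
    d <- p[(k + 1L):n, , drop = FALSE] - p[seq_len(n - k), , drop = FALSE]
    mean(rowSums(d * d))
  }, numeric(1))
  msd_curve(ks * traj$frame_interval, msd, n - ks, "time",
            traj$frame_interval)
}

#' Ensemble-averaged mean square displacement
#'
#' The unweighted mean of the member time-averaged MSD values at each lag,
#' over the trajectories that reach that lag; `n_pairs` counts contributing
#' trajectories.
#'
#' @param ensemble A [trajectory_ensemble()] with a common frame interval.
#' @param max_lag_k Largest lag index; default the largest lag any member
#'   reaches.
#' @return An `msd_curve` with attribute `kind = "ensemble"`.
#' @export
compute_eamsd <- function(ensemble, max_lag_k = NULL) {
  stopifnot(inherits(ensemble, "trajectory_ensemble"), length(ensemble) >= 1L)
  dts <- vapply(ensemble, `[[`, 0, "frame_interval")
  if (diff(range(dts)) > 1e-9) {
    stop("members must share a frame interval", call. = FALSE)
  }
  lens <- vapply(ensemble, n_frames, 0L)
  if (is.null(max_lag_k)) max_lag_k <- max(lens) - 1L
  if (!any(lens > max_lag_k)) {
    stop("no trajectory reaches max_lag_k", call. = FALSE)
  }
  acc <- matrix(NA_real_, length(ensemble), max_lag_k)
  for (i in seq_along(ensemble)) {
    ki <- min(max_lag_k, lens[i] - 1L)
    acc[i, seq_len(ki)] <- compute_tamsd(ensemble[[i]], ki)$msd_um2
  }
  msd_curve((seq_len(max_lag_k)) * dts[[1L]],
            colMeans(acc, na.rm = TRUE),
            colSums(!is.na(acc)), "ensemble", dts[[1L]])
}

#' Fit the anomalous-diffusion power law to an MSD curve
#'
#' Without an offset the fit is ordinary least squares of `ln MSD` on
#' `ln t`, giving `MSD(t) = 4 D_app t^beta` with `beta` the slope and
#' `D_app = exp(intercept) / 4`. With `with_offset = TRUE` a nonlinear
#' least-squares fit of `MSD = 4 D_app t^beta + 4 sigma^2` is performed
#' (Levenberg-Marquardt, `sigma^2 >= 0` constrained), initialized from the
#' log-log fit; the offset term estimates the localization-noise floor.
#'
#' @param msd An `msd_curve`.
#' @param lags Integer lag indices to fit. Default: the first quarter of the
#'   available lags (at least 3), a common single-particle-tracking choice;
#'   the range used is recorded in the result.
#' @param with_offset Fit the constant localization-noise offset?
#' @return A `power_law_fit` list: `D_app` (um^2 s^-beta), `beta`, `sigma`
#'   (um, `NA` without offset), `lags`, `r_squared` (on the fitted scale),
#'   `with_offset`.
#' @export
fit_msd_power_law <- function(msd, lags = NULL, with_offset = FALSE) {
  stopifnot(inherits(msd, "msd_curve"))
  K <- nrow(msd)
  if (is.null(lags)) lags <- seq_len(max(3L, K %/% 4L))
  lags <- as.integer(lags)
  if (any(lags < 1L | lags > K)) stop("lags out of range", call. = FALSE)
  if (length(lags) < 3L + as.integer(with_offset)) {
    stop("need at least 3 lag points (4 with offset)", call. = FALSE)
  }
  t <- msd$lag_s[lags]
  y <- msd$msd_um2[lags]
  if (any(y <= 0)) stop("non-positive MSD values in the fit range",
                        call. = FALSE)
  ll <- stats::lm(log(y) ~ log(t))
  beta0 <- unname(stats::coef(ll)[[2L]])
  D0 <- exp(unname(stats::coef(ll)[[1L]])) / 4
  if (!with_offset) {
    r2 <- rsq(log(y), stats::residuals(ll))
    return(structure(list(D_app = D0, beta = beta0, sigma = NA_real_,
                          lags = lags, r_squared = r2, with_offset = FALSE),
                     class = "power_law_fit"))
  }
  df <- data.frame(t = t, y = y)
  fit <- minpack.lm::nlsLM(y ~ 4 * D * t^b + 4 * s2, data = df,
                           start = list(D = D0, b = beta0, s2 = 0),
                           lower = c(D = 1e-14, b = 1e-9, s2 = 0),
                           control = minpack.lm::nls.lm.control(maxiter = 200))
  cf <- stats::coef(fit)
  r2 <- 1 - sum(stats::residuals(fit)^2) / sum((y - mean(y))^2)
  structure(list(D_app = unname(cf[["D"]]), beta = unname(cf[["b"]]),
                 sigma = sqrt(unname(cf[["s2"]])), lags = lags,
                 r_squared = r2, with_offset = TRUE),
            class = "power_law_fit")
}

#' @export
print.power_law_fit <- function(x, ...) {
  cat(sprintf("<power_law_fit> D_app = %.4g um^2 s^-beta, beta = %.3f",
              x$D_app, x$beta))
  if (x$with_offset) cat(sprintf(", sigma = %.4g um", x$sigma))
  cat(sprintf(" (lags %d..%d, R^2 = %.4f)\n",
              min(x$lags), max(x$lags), x$r_squared))
  invisible(x)
}

#' Short-time effective diffusion constant
#'
#' Ordinary least squares through the origin of the time-averaged MSD on lag
#' time over the first `n_lags` lags (default 4); `D_eff = slope / 4`. The
#' short-time window keeps the estimate in the regime where the confined
#' Langevin model looks like free diffusion.
#'
#' @param x A [locus_trajectory()] (needs >= 6 frames) or an `msd_curve`.
#' @param n_lags Number of initial lags used (recorded in the result).
#' @param ... Passed to methods.
#' @return A `diffusion_estimate` list: `D_eff` (um^2/s), `n_lags`, `lag_s`,
#'   and `degenerate` (`TRUE` for a constant trajectory, where `D_eff = 0`).
#' @export
estimate_deff <- function(x, n_lags = 4L, ...) UseMethod("estimate_deff")

#' @rdname estimate_deff
#' @export
estimate_deff.locus_trajectory <- function(x, n_lags = 4L, ...) {
  if (n_frames(x) < 6L) stop("need at least 6 frames", call. = FALSE)
  estimate_deff(compute_tamsd(x, min(n_lags, n_frames(x) - 1L)),
                n_lags = n_lags)
}

#' @rdname estimate_deff
#' @export
estimate_deff.msd_curve <- function(x, n_lags = 4L, ...) {
  n_lags <- min(n_lags, nrow(x))
  t <- x$lag_s[seq_len(n_lags)]
  y <- x$msd_um2[seq_len(n_lags)]
  slope <- sum(t * y) / sum(t * t)
  structure(list(D_eff = slope / 4, n_lags = n_lags, lag_s = t,
                 degenerate = all(y == 0)),
            class = "diffusion_estimate")
}

#' @export
print.diffusion_estimate <- function(x, ...) {
  cat(sprintf("<diffusion_estimate> D_eff = %.4g um^2/s (%d lags%s)\n",
              x$D_eff, x$n_lags, if (x$degenerate) ", degenerate" else ""))
  invisible(x)
}

#' Gyration (trajectory) radius
#'
#' `R_g = sqrt(mean |p(t) - p_C|^2)` with `p_C` the arithmetic mean of the
#' positions. The squared gyration radius is the "locus territory": the area
#' explored by the locus.
#'
#' @param traj A [locus_trajectory()].
#' @return A `trajectory_shape` list with `R_g` (um) and `centroid`.
#' @export
compute_rg <- function(traj) {
  stopifnot(inherits(traj, "locus_trajectory"))
  p <- traj$positions
  ctr <- colMeans(p)
  rg <- sqrt(mean(rowSums(sweep(p, 2L, ctr)^2)))
  structure(list(R_g = rg, centroid = ctr), class = "trajectory_shape")
}

#' Localization precision from immobilized beads
#'
#' Each bead trajectory is a nominally static emitter; the spread of its
#' localizations measures the optical system's localization precision. Per
#' bead the per-axis standard deviations and the radial RMS deviation
#' `sqrt(mean |p - p_mean|^2)` are computed, and their mean +/- s.d. over
#' beads is reported.
#'
#' @param bead_ensemble A [trajectory_ensemble()] of static bead recordings
#'   (>= 2 frames each).
#' @return A list with `per_bead` (data.frame `cell_id`, `sd_x_um`,
#'   `sd_y_um`, `rms_r_um`) and `summary` (data.frame `axis`, `mean_um`,
#'   `sd_um`).
#' @export
estimate_localization_precision <- function(bead_ensemble) {
  stopifnot(inherits(bead_ensemble, "trajectory_ensemble"),
            length(bead_ensemble) >= 1L)
  per <- do.call(rbind, lapply(bead_ensemble, function(tr) {
    p <- tr$positions
    if (nrow(p) < 2L) stop("bead trajectories need >= 2 frames", call. = FALSE)
    dev <- sweep(p, 2L, colMeans(p))
    data.frame(cell_id = tr$cell_id,
               sd_x_um = stats::sd(p[, 1L]),
               sd_y_um = stats::sd(p[, 2L]),
               rms_r_um = sqrt(mean(rowSums(dev * dev))),
               stringsAsFactors = FALSE)
  }))
  rownames(per) <- NULL
  summary <- data.frame(
    axis = c("x", "y", "radial"),
    mean_um = c(mean(per$sd_x_um), mean(per$sd_y_um), mean(per$rms_r_um)),
    sd_um = c(stats::sd(per$sd_x_um), stats::sd(per$sd_y_um),
              stats::sd(per$rms_r_um)),
    stringsAsFactors = FALSE)
  list(per_bead = per, summary = summary)
}

# coefficient of determination without summary.lm (avoids its perfect-fit
# warning on exact synthetic curves)
rsq <- function(y, resid) {
  sst <- sum((y - mean(y))^2)
  if (sst == 0) return(NA_real_)
  1 - sum(resid^2) / sst
}
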