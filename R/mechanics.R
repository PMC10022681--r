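# Effective spring constants from step-size regression under the overdamped
# Langevin model, the spring-vs-territory power law, and the Rouse tethering
# inversion. Energies are in units of k_B*T throughout, so the Einstein
# relation gives the friction coefficient gamma = 1 / D_eff and spring
# constants carry k_B*T um^-2.

#' Effective spring constant of a confined locus
#'
#' Under the overdamped Langevin model a harmonic restoring force
#' `-k_eff (p - p_C)` drives the expected step
#' `E[p((m+1)dt) - p(m dt)] = -(k_eff D_eff dt) (p(m dt) - p_C)` to first
#' order in `dt`. The slope `s` of the regression (through the origin) of
#' step components on centroid-relative position components, with x and y
#' pooled, therefore maps to `k_eff = -s / (D_eff * dt)`. The `"exact"`
#' method inverts the full Ornstein-Uhlenbeck decay factor,
#' `k_eff = -log(1 + s) / (D_eff * dt)`, which removes the first-order bias
#' (about 10% when `dt` is a fifth of the relaxation time).
#'
#' Free (unconfined) trajectories regress against the *sample* centroid and
#' therefore show a small negative finite-length artifact slope of order
#' `-3 / n_frames`; for trajectories of a few thousand frames this maps to a
#' spring constant far below genuinely confined values.
#'
#' @param traj A [locus_trajectory()] with >= 10 frames.
#' @param deff A `diffusion_estimate` for the same trajectory, or `NULL` to
#'   compute it with [estimate_deff()] defaults.
#' @param method `"linear"` (first-order slope mapping, the default) or
#'   `"exact"` (OU-exact mapping).
#' @return A `spring_estimate` list: `k_eff` (k_B*T um^-2; sign kept, with
#'   `flagged = TRUE` when the raw estimate is negative), `slope`,
#'   `slope_x`/`slope_y` per-axis diagnostics, `gamma` (k_B*T s um^-2),
#'   `D_eff`, `n_steps`, `method`.
#' @export
estimate_keff <- function(traj, deff = NULL, method = c("linear", "exact")) {
  stopifnot(inherits(traj, "locus_trajectory"))
  method <- match.arg(method)
  n <- n_frames(traj)
  if (n < 10L) stop("need at least 10 frames for step-size regression",
                    call. = FALSE)
  if (is.null(deff)) deff <- estimate_deff(traj)
  stopifnot(inherits(deff, "diffusion_estimate"))
  if (deff$degenerate || deff$D_eff <= 0) {
    stop("k_eff undefined for D_eff <= 0", call. = FALSE)
  }
  p <- traj$positions
  ctr <- colMeans(p)
  rel <- sweep(p[-n, , drop = FALSE], 2L, ctr)
  step <- p[-1L, , drop = FALSE] - p[-n, , drop = FALSE]
  slope <- sum(rel * step) / sum(rel * rel)
  slope_x <- sum(rel[, 1L] * step[, 1L]) / sum(rel[, 1L]^2)
  slope_y <- sum(rel[, 2L] * step[, 2L]) / sum(rel[, 2L]^2)
  dt <- traj$frame_interval
  k_eff <- if (method == "linear") {
    -slope / (deff$D_eff * dt)
  } else {
    if (slope <= -1) stop("slope <= -1: exact mapping undefined", call. = FALSE)
    -log1p(slope) / (deff$D_eff * dt)
  }
  structure(list(k_eff = k_eff, slope = slope,
                 slope_x = slope_x, slope_y = slope_y,
                 gamma = 1 / deff$D_eff, D_eff = deff$D_eff,
                 n_steps = n - 1L, method = method,
                 flagged = k_eff < 0),
            class = "spring_estimate")
}

#' @export
print.spring_estimate <- function(x, ...) {
  cat(sprintf("<spring_estimate> k_eff = %.4g k_BT/um^2 (slope %.4g, %d steps, %s mapping%s)\n",
              x$k_eff, x$slope, x$n_steps, x$method,
              if (x$flagged) ", flagged negative" else ""))
  invisible(x)
}

#' Fit the spring-constant-versus-territory power law
#'
#' Log-log ordinary least squares of `k_eff` on the locus territory `R_g^2`:
#' `<k_eff> = a <R_g^2>^-b`. For a thermally confined locus the stationary
#' identity `k Var = k_B T` per axis predicts `a = 2`, `b = 1` in two
#' dimensions.
#'
#' @param k_eff,rg2 Positive numeric vectors of matched spring constants
#'   (k_B*T um^-2) and squared gyration radii (um^2), >= 3 points.
#' @return A `spring_territory_fit` list: `a`, `b`, `n_points`, `r_squared`,
#'   `degenerate` (zero variance in the regressor).
#' @export
fit_keff_vs_territory <- function(k_eff, rg2) {
  stopifnot(length(k_eff) == length(rg2))
  ok <- is.finite(k_eff) & is.finite(rg2) & k_eff > 0 & rg2 > 0
  if (sum(ok) < 3L) stop("need >= 3 strictly positive points", call. = FALSE)
  x <- log(rg2[ok]); y <- log(k_eff[ok])
  if (stats::var(x) == 0) {
    return(structure(list(a = NA_real_, b = NA_real_, n_points = sum(ok),
                          r_squared = NA_real_, degenerate = TRUE),
                     class = "spring_territory_fit"))
  }
  fit <- stats::lm(y ~ x)
  structure(list(a = exp(unname(stats::coef(fit)[[1L]])),
                 b = -unname(stats::coef(fit)[[2L]]),
                 n_points = sum(ok),
                 r_squared = rsq(y, stats::residuals(fit)),
                 degenerate = FALSE),
            class = "spring_territory_fit")
}

#' @export
print.spring_territory_fit <- function(x, ...) {
  if (x$degenerate) {
    cat("<spring_territory_fit> degenerate (zero variance in R_g^2)\n")
  } else {
    cat(sprintf("<spring_territory_fit> k_eff = %.3f * (R_g^2)^-%.3f (n = %d, R^2 = %.3f)\n",
                x$a, x$b, x$n_points, x$r_squared))
  }
  invisible(x)
}

#' Predicted spring constant of a locus on a tethered Rouse chain
#'
#' Series-spring composition of the tether (`k_t`) and the chain segment of
#' genomic length `delta_c` between locus and tether (stiffness
#' `K_R / delta_c`):
#' `k_eff = k_t K_R / (K_R + delta_c k_t)`, i.e.
#' `1/k_eff = 1/k_t + delta_c / K_R`.
#'
#' `K_R` carries per-genomic-distance units (k_B*T um^-2 Mb) so the formula
#' is dimensionally consistent; this convention is used throughout.
#'
#' @param K_R Chain spring constant per genomic distance, k_B*T um^-2 Mb.
#' @param k_t Tether spring constant, k_B*T um^-2.
#' @param delta_c Genomic distance between locus and tether, Mb.
#' @return `k_eff` in k_B*T um^-2 (vectorized over `delta_c`).
#' @export
predict_keff_tethered <- function(K_R, k_t, delta_c) {
  stopifnot(K_R > 0, k_t > 0, all(delta_c > 0))
  k_t * K_R / (K_R + delta_c * k_t)
}

#' Infer tether and chain spring constants from measured locus stiffness
#'
#' Ordinary least squares of `1/k_eff_i` on `delta_c_i = |c_i - c_t|`
#' inverts the series-spring model: `K_R = 1/slope`, `k_t = 1/intercept`.
#' With exactly two loci this reproduces the closed two-locus formula
#' `K_R = (dc_1 - dc_2) k_1 k_2 / (k_2 - k_1)` identically. A negative
#' slope or intercept marks the solution infeasible (no positive spring
#' constants reproduce the measurements).
#'
#' With two loci and an unknown tether position the system is
#' under-determined, so the tether's genomic position `c_t` is a required
#' input. It must lie strictly outside the span of the measured loci (the
#' chain-segment lengths must all point towards one tether); set
#' `allow_inside = TRUE` only if you know what you are doing.
#'
#' @param c_i Genomic positions of the measured loci, Mb (>= 2, distinct).
#' @param k_eff Measured effective spring constants, k_B*T um^-2 (> 0).
#' @param c_t Genomic position of the tether, Mb.
#' @param allow_inside Permit `c_t` within the locus span.
#' @return A `tether_model` list: `K_R` (k_B*T um^-2 Mb), `k_t`
#'   (k_B*T um^-2), `c_t`, `feasible`, and the `loci` data.frame
#'   (`c_mb`, `delta_c_mb`, `k_eff`).
#' @export
infer_tether <- function(c_i, k_eff, c_t, allow_inside = FALSE) {
  stopifnot(length(c_i) == length(k_eff))
  if (length(c_i) < 2L) stop("need at least 2 loci", call. = FALSE)
  if (any(k_eff <= 0)) stop("k_eff values must be positive", call. = FALSE)
  if (!allow_inside && c_t > min(c_i) && c_t < max(c_i)) {
    stop("c_t lies inside the span of the measured loci; pass allow_inside = TRUE to override",
         call. = FALSE)
  }
  dc <- abs(c_i - c_t)
  if (any(dc == 0)) stop("a locus coincides with the tether", call. = FALSE)
  if (length(unique(dc)) < 2L) {
    stop("delta_c values are all equal; the regression is degenerate",
         call. = FALSE)
  }
  fit <- stats::lm(I(1 / k_eff) ~ dc)
  slope <- unname(stats::coef(fit)[[2L]])
  intercept <- unname(stats::coef(fit)[[1L]])
  feasible <- slope > 0 && intercept > 0
  structure(list(K_R = 1 / slope, k_t = 1 / intercept, c_t = c_t,
                 feasible = feasible,
                 loci = data.frame(c_mb = c_i, delta_c_mb = dc,
                                   k_eff = k_eff)),
            class = "tether_model")
}

#' @export
print.tether_model <- function(x, ...) {
  cat(sprintf("<tether_model> K_R = %.4g k_BT um^-2 Mb, k_t = %.4g k_BT um^-2 (c_t = %g Mb%s)\n",
              x$K_R, x$k_t, x$c_t,
              if (x$feasible) "" else ", INFEASIBLE"))
  invisible(x)
}
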