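test_that("TA-MSD matches the hand-evaluated definition", {
  tr <- make_traj(c(0, 1, 2), c(0, 0, 0))
  msd <- compute_tamsd(tr)
  expect_equal(msd$msd_um2, c(1, 4))
  expect_equal(msd$n_pairs, c(2, 1))
  expect_equal(msd$lag_s, c(1, 2))

  const <- make_traj(rep(2, 10), rep(-1, 10))
  expect_equal(compute_tamsd(const)$msd_um2, rep(0, 9))

  expect_error(compute_tamsd(tr, 3), "max_lag_k")
})

test_that("MSD, R_g and D_eff are invariant under rigid motions", {
  tr <- random_walk_traj(40, seed = 21)
  moved <- rigid_transform(tr, theta = 0.83, shift = c(-3, 7))
  expect_equal(compute_tamsd(moved)$msd_um2, compute_tamsd(tr)$msd_um2,
               tolerance = 1e-12)
  expect_equal(compute_rg(moved)$R_g, compute_rg(tr)$R_g, tolerance = 1e-12)
  expect_equal(estimate_deff(moved)$D_eff, estimate_deff(tr)$D_eff,
               tolerance = 1e-12)
})

test_that("EA-MSD averages member TA-MSDs and degenerates to TA-MSD", {
  tr1 <- random_walk_traj(30, seed = 22)
  tr2 <- random_walk_traj(30, seed = 23)
  solo <- compute_eamsd(trajectory_ensemble(list(tr1)), 10)
  expect_equal(solo$msd_um2, compute_tamsd(tr1, 10)$msd_um2)

  both <- compute_eamsd(trajectory_ensemble(list(tr1, tr2)), 10)
  expect_equal(both$msd_um2,
               (compute_tamsd(tr1, 10)$msd_um2 +
                  compute_tamsd(tr2, 10)$msd_um2) / 2)
  expect_equal(both$n_pairs, rep(2L, 10))

  # members of different length contribute only up to their reach
  short <- random_walk_traj(6, seed = 24)
  mix <- compute_eamsd(trajectory_ensemble(list(tr1, short)), 10)
  expect_equal(mix$n_pairs, c(rep(2L, 5), rep(1L, 5)))
})

test_that("EA-MSD of free diffusion follows 4 D t", {
  ens <- simulate_brownian(0.01, n_trajectories = 200, n_frames = 120,
                           frame_interval = 1, seed = 25)
  msd <- compute_eamsd(ens, 5)
  expect_equal(msd$msd_um2 / (4 * msd$lag_s), rep(0.01, 5), tolerance = 0.1)
})

test_that("power-law fit recovers its own model exactly", {
  t <- 1:10
  curve <- msd_curve <- structure(
    data.frame(lag_s = t, msd_um2 = 4 * 0.01 * t^0.5, n_pairs = 10:1),
    class = c("msd_curve", "data.frame"))
  fit <- fit_msd_power_law(curve, lags = 1:10)
  expect_equal(fit$D_app, 0.01, tolerance = 1e-10)
  expect_equal(fit$beta, 0.5, tolerance = 1e-10)
  expect_equal(fit$r_squared, 1, tolerance = 1e-10)

  withoff <- structure(
    data.frame(lag_s = t, msd_um2 = 4 * 0.01 * t + 4 * 0.05^2,
               n_pairs = 10:1),
    class = c("msd_curve", "data.frame"))
  fit2 <- fit_msd_power_law(withoff, lags = 1:10, with_offset = TRUE)
  expect_equal(fit2$D_app, 0.01, tolerance = 1e-6)
  expect_equal(fit2$beta, 1, tolerance = 1e-6)
  expect_equal(fit2$sigma, 0.05, tolerance = 1e-6)

  bad <- structure(data.frame(lag_s = t, msd_um2 = c(0, rep(1, 9)),
                              n_pairs = 10:1),
                   class = c("msd_curve", "data.frame"))
  expect_error(fit_msd_power_law(bad, lags = 1:10), "non-positive")
})

test_that("D_eff is the origin-constrained initial MSD slope", {
  # exactly linear MSD: slope / 4 recovers D for any lag subset
  curve <- structure(data.frame(lag_s = 1:6, msd_um2 = 4 * 0.004 * (1:6),
                                n_pairs = 6:1),
                     class = c("msd_curve", "data.frame"))
  expect_equal(estimate_deff(curve)$D_eff, 0.004, tolerance = 1e-12)
  expect_equal(estimate_deff(curve, n_lags = 2)$n_lags, 2L)

  const <- make_traj(rep(1, 12), rep(1, 12))
  est <- estimate_deff(const)
  expect_true(est$degenerate)
  expect_equal(est$D_eff, 0)
  expect_error(estimate_deff(make_traj(1:3, 1:3)), "6 frames")
})

test_that("mean D_eff recovers the generating diffusion constant", {
  ens <- simulate_brownian(0.0035, n_trajectories = 200, seed = 26)
  deff <- vapply(ens, function(t) estimate_deff(t)$D_eff, numeric(1))
  expect_equal(mean(deff), 0.0035, tolerance = 0.05)

  # confined motion with relaxation time >> the 4-lag window still looks free
  k <- 4  # tau = 1/(D k) ~ 71 s >> 4 * 0.667 s
  ou <- simulate_ou(k, 0.0035, n_trajectories = 100, seed = 27)
  deff_ou <- vapply(ou, function(t) estimate_deff(t)$D_eff, numeric(1))
  expect_equal(mean(deff_ou), 0.0035, tolerance = 0.1)
})

test_that("gyration radius matches hand-computed values", {
  expect_equal(compute_rg(make_traj(c(1, 1), c(2, 2)))$R_g, 0)
  expect_equal(compute_rg(make_traj(c(0, 0.2), c(0, 0)))$R_g, 0.1)
  sq <- make_traj(c(0, 1, 1, 0), c(0, 0, 1, 1))
  expect_equal(compute_rg(sq)$R_g, sqrt(0.5))
  expect_equal(compute_rg(sq)$centroid, c(x_um = 0.5, y_um = 0.5))
})

test_that("localization precision is recovered from static bead stacks", {
  clean <- trajectory_ensemble(lapply(1:5, function(i) {
    make_traj(rep(i, 10), rep(-i, 10), cell = sprintf("bead%d", i))
  }))
  res <- estimate_localization_precision(clean)
  expect_equal(res$summary$mean_um, rep(0, 3))

  noisy <- add_localization_noise(trajectory_ensemble(lapply(1:50, function(i) {
    make_traj(rep(i, 200), rep(0, 200), cell = sprintf("bead%d", i))
  })), sigma = 0.006, seed = 28)
  res2 <- estimate_localization_precision(noisy)
  expect_equal(res2$summary$mean_um[res2$summary$axis == "x"], 0.006,
               tolerance = 0.1)
  expect_equal(res2$summary$mean_um[res2$summary$axis == "radial"],
               0.006 * sqrt(2), tolerance = 0.1)

  # common offset to every bead leaves precision unchanged
  shifted <- trajectory_ensemble(lapply(noisy, function(tr) {
    make_traj(tr$positions[, 1L] + 100, tr$positions[, 2L] + 100,
              cell = tr$cell_id)
  }))
  expect_equal(estimate_localization_precision(shifted)$summary$mean_um,
               res2$summary$mean_um, tolerance = 1e-9)
})
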