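test_that("step-size regression slope matches an independent lm oracle", {
  tr <- random_walk_traj(60, seed = 31)
  est <- estimate_keff(tr, deff = estimate_deff(tr))
  p <- tr$positions
  n <- nrow(p)
  rel <- sweep(p[-n, ], 2, colMeans(p))
  step <- diff(p)
  oracle <- unname(coef(lm(c(step) ~ 0 + c(rel))))
  expect_equal(est$slope, oracle, tolerance = 1e-12)
  # slope-to-spring algebra
  expect_equal(est$k_eff, -est$slope / (est$D_eff * tr$frame_interval),
               tolerance = 1e-12)
})

test_that("k_eff estimation is invariant under rigid motions", {
  set.seed(32)
  tr <- simulate_ou(100, 0.0035, n_frames = 300, frame_interval = 0.1)[[1L]]
  moved <- rigid_transform(tr, theta = 1.2, shift = c(10, -4))
  expect_equal(estimate_keff(moved)$k_eff, estimate_keff(tr)$k_eff,
               tolerance = 1e-9)
})

test_that("free Brownian motion shows only the small finite-length artifact", {
  # regressing against the sample centroid gives a slope of order -3/n for a
  # free walk; with long trajectories this maps to a spring constant far
  # below genuinely confined values (tens to hundreds of k_BT/um^2)
  n <- 2000L
  ens <- simulate_brownian(0.0035, n_trajectories = 100, n_frames = n,
                           seed = 33)
  ests <- lapply(ens, estimate_keff)
  slopes <- vapply(ests, `[[`, 0, "slope")
  keff <- vapply(ests, `[[`, 0, "k_eff")
  expect_lt(abs(mean(slopes)), 5 / n)
  expect_lt(abs(mean(keff)), 2)
})

test_that("k_eff recovers the generating OU spring constant", {
  # trajectories must span many relaxation times: regressing against the
  # sample centroid inflates k_eff by O(tau / T_total), ~10% at 40 tau and
  # ~4% at the 120 tau used here
  k <- 100; D <- 0.0035
  dt <- 0.02 / (D * k)  # frame interval at 2% of the relaxation time
  ens <- simulate_ou(k, D, n_trajectories = 100, n_frames = 6000,
                     frame_interval = dt, seed = 34)
  keff <- vapply(ens, function(t) estimate_keff(t)$k_eff, numeric(1))
  expect_equal(mean(keff), k, tolerance = 0.1)
  # the exact OU mapping agrees at this short sampling interval
  kexact <- vapply(ens, function(t) estimate_keff(t, method = "exact")$k_eff,
                   numeric(1))
  expect_equal(mean(kexact), mean(keff), tolerance = 0.05)
})

test_that("deterministic contraction yields the exact regression slope", {
  # relative positions contract by 10% per frame; regressing the change on
  # the relative position gives exactly -0.1 when centered coordinates are
  # used, so we verify on a trajectory whose centroid is known by symmetry
  x <- 0.9^(0:19)
  tr <- make_traj(x, rep(0, 20))
  p <- tr$positions
  rel <- sweep(p[-20, ], 2, colMeans(p))
  step <- diff(p)
  slope_manual <- sum(rel * step) / sum(rel * rel)
  est <- estimate_keff(tr, deff = estimate_deff(tr))
  expect_equal(est$slope, slope_manual, tolerance = 1e-12)
  expect_lt(est$slope, 0)
})

test_that("territory fit inverts its own power law and flags degeneracy", {
  rg2 <- c(0.01, 0.02, 0.04, 0.08)
  fit <- fit_keff_vs_territory(2 / rg2, rg2)
  expect_equal(fit$a, 2, tolerance = 1e-10)
  expect_equal(fit$b, 1, tolerance = 1e-10)

  flat <- fit_keff_vs_territory(c(1, 2, 3), rep(0.02, 3))
  expect_true(flat$degenerate)
  expect_error(fit_keff_vs_territory(c(1, -1, 2), c(1, 1, 1)), "positive")
})

test_that("stationary identity ties k_eff, R_g and the territory law together", {
  # long confined trajectories: k_eff * R_g^2 -> 2 k_BT in two dimensions
  k <- 50; D <- 0.0035
  dt <- 0.05 / (D * k)
  ens <- simulate_ou(k, D, n_trajectories = 50, n_frames = 3000,
                     frame_interval = dt, seed = 35)
  prod <- vapply(ens, function(t) {
    estimate_keff(t)$k_eff * compute_rg(t)$R_g^2
  }, numeric(1))
  expect_equal(mean(prod), 2, tolerance = 0.1)
})

test_that("tethered-chain spring prediction follows the series-spring law", {
  expect_equal(predict_keff_tethered(100, 60, 5), 15)
  expect_equal(predict_keff_tethered(100, 60, 2.7), 1 / (1 / 60 + 2.7 / 100))
  # limits: short segment -> tether dominates; stiff tether -> chain segment
  expect_equal(predict_keff_tethered(100, 60, 1e-9), 60, tolerance = 1e-6)
  expect_equal(predict_keff_tethered(100, 1e9, 5), 20, tolerance = 1e-6)
  # monotonicity
  dc <- c(0.5, 1, 2, 4, 8)
  expect_true(all(diff(predict_keff_tethered(100, 60, dc)) < 0))
  expect_error(predict_keff_tethered(-1, 60, 5))
})

test_that("tether inversion recovers the generating constants exactly", {
  k <- predict_keff_tethered(100, 60, c(5, 2.7))
  tm <- infer_tether(c_i = c(5, 7.3), k_eff = k, c_t = 10)
  expect_equal(tm$K_R, 100, tolerance = 1e-9)
  expect_equal(tm$k_t, 60, tolerance = 1e-9)
  expect_true(tm$feasible)

  # the regression path reproduces the closed two-locus formula identically
  dc <- c(5, 2.7)
  KR_closed <- (dc[1] - dc[2]) * k[1] * k[2] / (k[2] - k[1])
  expect_equal(tm$K_R, KR_closed, tolerance = 1e-12)
})

test_that("forward model and inversion are inverse over random admissible draws", {
  set.seed(36)
  for (i in 1:200) {
    K_R <- runif(1, 5, 500)
    k_t <- runif(1, 5, 800)
    c_t <- runif(1, 20, 40)
    c_i <- sort(runif(sample(2:5, 1), 0, 19))
    k <- predict_keff_tethered(K_R, k_t, abs(c_i - c_t))
    tm <- infer_tether(c_i, k, c_t)
    expect_equal(tm$K_R, K_R, tolerance = 1e-9)
    expect_equal(tm$k_t, k_t, tolerance = 1e-9)
  }
})

test_that("tether inversion rejects bad inputs and flags infeasible fits", {
  expect_error(infer_tether(1, 10, c_t = 5), "at least 2")
  expect_error(infer_tether(c(1, 2), c(10, 20), c_t = 1.5), "inside")
  expect_error(infer_tether(c(4, 6), c(10, 20), c_t = 5, allow_inside = TRUE),
               "equal")
  # k_eff increasing with delta_c cannot come from a positive tether model
  tm <- infer_tether(c(1, 2), c(10, 20), c_t = 10)
  expect_false(tm$feasible)
})

test_that("tether constants are recovered from a simulated tethered chain", {
  # 16-bead chain tethered at one end; spring constants measured at three
  # labeled beads by step-size regression with a single-lag D_eff (which
  # reduces the estimator to the stationary-variance identity and keeps it
  # valid for non-Markovian bead motion), then inverted for (K_R, k_t)
  k_s <- 10; k_t <- 5; D <- 0.01; spacing <- 1
  spec <- rouse_chain_spec(16, k_s, D,
                           tether = list(bead = 16, anchor = c(0, 0),
                                         k_t = k_t),
                           labeled_beads = c(1, 8, 12),
                           genomic_spacing = spacing)
  tau <- chromotrace:::rouse_slowest_time(spec)
  ens <- simulate_rouse_chain(spec, n_trajectories = 30, n_frames = 60,
                              frame_interval = tau, seed = 61)
  kmeas <- vapply(c(1, 8, 12), function(b) {
    sub <- Filter(function(t) t$meta$bead == b, ens)
    mean(vapply(sub, function(t) {
      estimate_keff(t, deff = estimate_deff(t, n_lags = 1))$k_eff
    }, numeric(1)))
  }, numeric(1))
  # per-bead truth from the equilibrium spring algebra
  ktrue <- 1 / (1 / k_t + (16 - c(1, 8, 12)) * spacing / (k_s * spacing))
  expect_equal(unname(kmeas), ktrue, tolerance = 0.15)

  tm <- infer_tether(c_i = (c(1, 8, 12) - 1) * spacing, k_eff = kmeas,
                     c_t = 15 * spacing)
  expect_equal(tm$K_R, k_s * spacing, tolerance = 0.25)
  expect_equal(tm$k_t, k_t, tolerance = 0.25)
})
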