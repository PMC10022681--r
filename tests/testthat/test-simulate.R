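test_that("Brownian generator obeys its increment law and is reproducible", {
  expect_equal(simulate_brownian(0, n_frames = 50, seed = 1)[[1L]]$positions,
               matrix(0, 50, 2, dimnames = list(NULL, c("x_um", "y_um"))))

  tr <- simulate_brownian(0.01, n_frames = 10001L, frame_interval = 1,
                          seed = 2)[[1L]]
  steps <- diff(tr$positions)
  expect_equal(var(as.vector(steps)), 2 * 0.01, tolerance = 0.05)

  a <- simulate_brownian(0.01, n_trajectories = 3, seed = 7)
  b <- simulate_brownian(0.01, n_trajectories = 3, seed = 7)
  expect_identical(as.data.frame(a), as.data.frame(b))
})

test_that("OU generator has the exact stationary law", {
  # frames spaced 5 relaxation times apart: effectively independent samples
  k <- 100; D <- 0.0035
  dt <- 5 / (D * k)
  ens <- simulate_ou(k, D, n_trajectories = 100, n_frames = 1000,
                     frame_interval = dt, seed = 3)
  xs <- unlist(lapply(ens, function(t) as.vector(t$positions)))
  expect_equal(var(xs), 1 / k, tolerance = 0.03)
  # consecutive positions decorrelated at large lag
  r <- cor(ens[[1L]]$positions[-1000, 1L], ens[[1L]]$positions[-1L, 1L])
  expect_lt(abs(r), 0.1)
})

test_that("OU center and k = 0 fallback behave as documented", {
  ens <- simulate_ou(50, 0.01, center = c(5, 5), n_trajectories = 200,
                     n_frames = 2, frame_interval = 100, seed = 4)
  p <- do.call(rbind, lapply(ens, `[[`, "positions"))
  expect_equal(colMeans(p), c(x_um = 5, y_um = 5), tolerance = 0.05)

  a <- simulate_ou(0, 0.01, n_trajectories = 2, seed = 5)
  b <- simulate_brownian(0.01, n_trajectories = 2, seed = 5)
  expect_identical(as.data.frame(a), as.data.frame(b))
})

test_that("fBm at beta = 1 reduces to Brownian statistics", {
  ens <- simulate_fbm(1, 0.01, n_trajectories = 50, n_frames = 200,
                      frame_interval = 1, seed = 6)
  steps <- do.call(rbind, lapply(ens, function(t) diff(t$positions)))
  expect_equal(var(as.vector(steps)), 0.02, tolerance = 0.05)
  # increments uncorrelated at beta = 1
  s1 <- diff(ens[[1L]]$positions[, 1L])
  expect_lt(abs(cor(s1[-1L], s1[-length(s1)])), 0.2)
})

test_that("fBm ensemble MSD recovers the generating exponent", {
  ens <- simulate_fbm(0.4, 0.003, n_trajectories = 200, seed = 8)
  fit <- fit_msd_power_law(compute_eamsd(ens, 30))
  expect_gte(fit$beta, 0.35)
  expect_lte(fit$beta, 0.45)
  a <- simulate_fbm(0.4, 0.003, n_trajectories = 2, seed = 9)
  b <- simulate_fbm(0.4, 0.003, n_trajectories = 2, seed = 9)
  expect_identical(as.data.frame(a), as.data.frame(b))
  expect_error(simulate_fbm(2.1, 0.01), "beta")
})

test_that("localization noise adds an independent flat MSD floor", {
  ens <- simulate_brownian(0.01, n_trajectories = 2, seed = 10)
  expect_identical(add_localization_noise(ens, 0), ens)

  static <- simulate_brownian(0, n_frames = 10000L, frame_interval = 1)
  noisy <- add_localization_noise(static, 0.05, seed = 11)[[1L]]
  msd <- compute_tamsd(noisy, 20)
  expect_equal(msd$msd_um2, rep(4 * 0.05^2, 20), tolerance = 0.1)
  # offsets independent across frames
  off <- noisy$positions[, 1L]
  expect_lt(abs(cor(off[-1L], off[-length(off)])), 0.05)
})

test_that("nucleus simulation places loci at exact target radial fractions", {
  out <- simulate_nucleus("n1", c(2, -1), a = 10, b = 10, theta = 0,
                          loci = data.frame(locus_id = c("A", "B"),
                                            nrd = c(0.5, 0),
                                            angle = c(pi / 3, 0)))
  expect_equal(sqrt(sum((unlist(out$loci[1L, c("x_um", "y_um")]) -
                           c(2, -1))^2)), 5, tolerance = 1e-12)
  expect_equal(unlist(out$loci[2L, c("x_um", "y_um")]),
               c(x_um = 2, y_um = -1), tolerance = 1e-12)

  ell <- simulate_nucleus("n2", c(0, 0), a = 10, b = 5, theta = 0,
                          loci = data.frame(locus_id = "C", nrd = 0.8,
                                            angle = 0))
  expect_equal(unlist(ell$loci[, c("x_um", "y_um")]),
               c(x_um = 8, y_um = 0), tolerance = 1e-12)
  # round trip through compute_nrd is exact
  rec <- compute_nrd(c(8, 0), ell$geometry)
  expect_equal(rec$nrd, 0.8, tolerance = 1e-9)

  expect_error(simulate_nucleus("n3", c(0, 0), 1, 1,
                                loci = data.frame(locus_id = "D", nrd = 1.2,
                                                  angle = 0)),
               "NRD")
})

test_that("pair-distance generator reproduces the exact power law without noise", {
  ps <- generate_pair_distances(0.2, 0.4, c(29, 4.62), n_cells = 2,
                                n_frames = 5, seed = 12)
  expect_equal(ps[[1L]]$distances, rep(0.4 * 29^0.2, 5))
  expect_equal(ps[[3L]]$distances, rep(0.4 * 4.62^0.2, 5))
  # spot value of the power law itself
  expect_equal(0.4 * 29^0.2, 0.7844, tolerance = 1e-3)
})

test_that("single tethered bead matches the OU stationary variance", {
  k_t <- 100; D <- 0.0035
  spec <- rouse_chain_spec(1, neighbor_spring = 0, bead_diffusion = D,
                           tether = list(bead = 1, anchor = c(0, 0),
                                         k_t = k_t))
  ens <- simulate_rouse_chain(spec, n_trajectories = 100, n_frames = 30,
                              frame_interval = 3 / (D * k_t), seed = 13)
  xs <- unlist(lapply(ens, function(t) as.vector(t$positions)))
  expect_equal(var(xs), 1 / k_t, tolerance = 0.1)
})

test_that("untethered chain center of mass diffuses with D/n", {
  n_beads <- 4; D <- 0.01
  spec <- rouse_chain_spec(n_beads, 10, D, labeled_beads = 1:n_beads)
  ens <- simulate_rouse_chain(spec, n_trajectories = 30, n_frames = 60,
                              frame_interval = 2, seed = 14)
  by_chain <- split_ensemble(ens, "cell_id")
  deff <- vapply(by_chain, function(chain) {
    com_x <- rowMeans(vapply(chain, function(t) t$positions[, 1L],
                             numeric(60)))
    com_y <- rowMeans(vapply(chain, function(t) t$positions[, 2L],
                             numeric(60)))
    estimate_deff(make_traj(com_x, com_y, dt = 2))$D_eff
  }, numeric(1))
  expect_equal(mean(deff), D / n_beads, tolerance = 0.2)
})

test_that("Rouse generator is bit-reproducible under a fixed seed", {
  spec <- rouse_chain_spec(4, 10, 0.01, labeled_beads = c(1, 4))
  a <- simulate_rouse_chain(spec, n_trajectories = 2, n_frames = 5,
                            frame_interval = 1, seed = 15)
  b <- simulate_rouse_chain(spec, n_trajectories = 2, n_frames = 5,
                            frame_interval = 1, seed = 15)
  expect_identical(as.data.frame(a), as.data.frame(b))
})
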