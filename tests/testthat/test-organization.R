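test_that("pair distances are per-frame Euclidean and rigid-motion invariant", {
  a <- make_traj(rep(0, 5), rep(0, 5), cell = "c1", locus = "A")
  b <- make_traj(rep(3, 5), rep(4, 5), cell = "c1", locus = "B")
  ps <- compute_pair_distance_series(a, b, genomic_distance = 2)
  expect_equal(ps$distances, rep(5, 5))
  expect_identical(ps$pair, "A/B")

  expect_equal(compute_pair_distance_series(a, a, 1)$distances, rep(0, 5))

  a2 <- rigid_transform(a, theta = 0.7, shift = c(2, -1))
  b2 <- rigid_transform(b, theta = 0.7, shift = c(2, -1))
  expect_equal(compute_pair_distance_series(a2, b2, 2)$distances,
               ps$distances, tolerance = 1e-12)

  other_cell <- make_traj(rep(3, 5), rep(4, 5), cell = "c2", locus = "B")
  expect_error(compute_pair_distance_series(a, other_cell, 1), "same cell")
  short <- make_traj(rep(3, 4), rep(4, 4), cell = "c1", locus = "B")
  expect_error(compute_pair_distance_series(a, short, 1), "frame mismatch")
})

test_that("population pair distance averages time first, then cells", {
  s1 <- locus_pair_series("c1", "A/B", 2, rep(0.4, 30))
  s2 <- locus_pair_series("c2", "A/B", 2, rep(0.6, 30))
  res <- mean_pair_distance(list(s1, s2))
  expect_equal(res$mean_r, 0.5)
  expect_equal(res$per_cell$mean_r_um, c(0.4, 0.6))
  expect_error(mean_pair_distance(list(locus_pair_series("c", "p", 1,
                                                         rep(1, 10)))),
               "fewer than 30")
})

test_that("compaction fit inverts its own power law and supports nested spans", {
  s <- c(1.93, 2.69, 4.62)
  fit <- fit_compaction(s, 0.4 * s^0.40)
  expect_equal(fit$delta, 0.40, tolerance = 1e-10)
  expect_equal(fit$prefactor, 0.4, tolerance = 1e-10)

  s_all <- c(1.93, 2.69, 4.62, 25.82, 29.05)
  nested <- fit_compaction(s_all, 0.4 * s_all^0.2,
                           spans = c(span5 = 5, span30 = 30))
  expect_equal(nested$span_fits$span5$delta, 0.2, tolerance = 1e-10)
  expect_equal(nrow(nested$span_fits$span5$points), 3L)
  expect_error(fit_compaction(c(1, 2), c(-1, 1)), "positive")
  expect_error(fit_compaction(c(2, 2), c(1, 1)), "distinct")
})

test_that("variation decomposition separates cell and temporal spread", {
  same <- lapply(1:4, function(i) locus_pair_series(paste0("c", i), "p", 1,
                                                    rep(0.7, 20)))
  dv <- decompose_variation(same)
  expect_equal(dv$cell_sd, 0)
  expect_equal(dv$mean_temporal_dev, 0)

  # temporal deviations unchanged by per-cell constant offsets
  set.seed(41)
  base <- lapply(1:10, function(i) {
    locus_pair_series(paste0("c", i), "p", 1, 1 + rnorm(50, sd = 0.1))
  })
  shifted <- lapply(seq_along(base), function(i) {
    locus_pair_series(base[[i]]$cell_id, "p", 1,
                      base[[i]]$distances + i * 0.5)
  })
  expect_equal(decompose_variation(shifted)$temporal_deviations,
               decompose_variation(base)$temporal_deviations)
})

test_that("decomposition recovers the generator's two variation sources", {
  ps <- generate_pair_distances(0.2, 0.4, c(s29 = 29.05), cell_sd = 0.3,
                                temporal_sd = 0.1, n_cells = 200,
                                n_frames = 30, seed = 42)
  dv <- decompose_variation(ps)
  expect_equal(dv$cell_sd, 0.3, tolerance = 0.15)
  expect_equal(dv$mean_temporal_dev, 0.1 * sqrt(2 / pi), tolerance = 0.1)
  expect_equal(dv$implied_temporal_sd, 0.1, tolerance = 0.1)
  # total variance decomposes additively for the Gaussian generator
  all_r <- unlist(lapply(ps, `[[`, "distances"))
  expect_equal(var(all_r), 0.3^2 + 0.1^2, tolerance = 0.1)
})

test_that("NRD follows the ray definition on circles, ellipses and edge cases", {
  circ <- nucleus_geometry("n", c(0, 0), ellipse_boundary(c(0, 0), 10, 10))
  expect_equal(compute_nrd(c(3, 4), circ)$nrd, 0.5)
  expect_equal(compute_nrd(c(0, 10), circ)$nrd, 1)
  expect_equal(compute_nrd(c(0, 0), circ)$nrd, 0)

  ell <- nucleus_geometry("n", c(0, 0), ellipse_boundary(c(0, 0), 10, 5))
  expect_equal(compute_nrd(c(4, 0), ell)$nrd, 0.4)
  expect_equal(compute_nrd(c(0, 4), ell)$nrd, 0.8)

  # marginally outside: clipped and flagged; grossly outside: error
  rec <- compute_nrd(c(10.2, 0), circ)
  expect_equal(rec$nrd, 1)
  expect_true(rec$clipped)
  expect_error(compute_nrd(c(11, 0), circ), "outside")
})

test_that("polygon NRD agrees with the ellipse closed form", {
  theta <- seq(0, 2 * pi, length.out = 257)[-257]
  poly <- polygon_boundary(cbind(7 * cos(theta), 3 * sin(theta)))
  gp <- nucleus_geometry("n", c(0, 0), poly)
  ge <- nucleus_geometry("n", c(0, 0), ellipse_boundary(c(0, 0), 7, 3))
  set.seed(43)
  for (i in 1:25) {
    ang <- runif(1, 0, 2 * pi)
    r <- runif(1, 0, 0.95)
    pt <- c(r * 7 * cos(ang), r * 3 * sin(ang))
    expect_equal(compute_nrd(pt, gp)$nrd, compute_nrd(pt, ge)$nrd,
                 tolerance = 1e-3)
  }
})

test_that("NRD distributions give right-continuous CDFs and honest histograms", {
  one <- nrd_distribution(0.8)
  expect_equal(one$cdf(0.79), 0)
  expect_equal(one$cdf(0.8), 1)
  expect_equal(sum(one$histogram$count), 1)

  set.seed(44)
  u <- runif(2000)
  nd <- nrd_distribution(u)
  expect_equal(nd$cdf(1), 1)
  # DKW band around the uniform diagonal at alpha = 0.01
  grid <- seq(0, 1, by = 0.001)
  eps <- sqrt(log(2 / 0.01) / (2 * length(u)))
  expect_lt(max(abs(nd$cdf(grid) - grid)), eps)
  expect_equal(sum(nd$histogram$count), 2000)
})

test_that("mobility-position correlation matches a direct covariance oracle", {
  nrd <- c(0.1, 0.2, 0.3)
  deff <- c(1, 2, 1)
  res <- correlate_mobility_position(nrd, deff)
  oracle <- sum((nrd - mean(nrd)) * (deff - mean(deff))) /
    sqrt(sum((nrd - mean(nrd))^2) * sum((deff - mean(deff))^2))
  expect_equal(res$r, oracle, tolerance = 1e-12)

  exact <- correlate_mobility_position(c(0.1, 0.5, 0.9), 2 * c(0.1, 0.5, 0.9))
  expect_equal(exact$r, 1)
  expect_identical(exact$class, "moderate+")

  set.seed(45)
  null <- correlate_mobility_position(runif(10000), rnorm(10000))
  expect_lt(abs(null$r), 0.05)
  expect_identical(null$class, "negligible")
  # exact r = 0.3 built from orthogonal components -> "weak"
  x <- c(1, -1, 1, -1)
  y <- 0.3 * x + sqrt(1 - 0.3^2) * c(1, 1, -1, -1)
  weak <- correlate_mobility_position((x + 2) / 4, y)
  expect_equal(weak$r, 0.3, tolerance = 1e-12)
  expect_identical(weak$class, "weak")

  expect_error(correlate_mobility_position(rep(0.5, 5), 1:5), "zero variance")
})
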