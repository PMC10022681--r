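# Shared fixture builders for the test suite. All fixtures are generated in
# code; trajectories use micrometre/second units throughout.

make_traj <- function(x, y, dt = 1, cell = "c1", locus = "L1", ...) {
  locus_trajectory(cell, locus, times = (seq_along(x) - 1) * dt,
                   x = x, y = y, ...)
}

# apply a rigid motion (rotation by theta about the origin, then translation)
rigid_transform <- function(traj, theta = 0, shift = c(0, 0)) {
  R <- matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2L)
  p <- traj$positions %*% t(R)
  p <- sweep(p, 2L, -shift)
  make_traj(p[, 1L], p[, 2L], dt = traj$frame_interval,
            cell = traj$cell_id, locus = traj$locus_id)
}

random_walk_traj <- function(n = 50, dt = 1, sd = 0.1, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  make_traj(cumsum(rnorm(n, sd = sd)), cumsum(rnorm(n, sd = sd)), dt = dt)
}

write_traj_csv <- function(lines, path = tempfile(fileext = ".csv")) {
  writeLines(lines, path)
  path
}
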