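#include <Rcpp.h>
using namespace Rcpp;

// Overdamped Euler-Maruyama integration of independent Rouse chains:
// nearest-neighbor harmonic springs (stiffness k_s, units k_B*T um^-2) and
// an optional harmonic tether of one bead to a fixed lab-frame anchor.
// Mobility equals the bead diffusion constant D (energies in k_B*T).
//
// state: (n_traj * n_beads) x 2 matrix, chain-major (trajectory t occupies
// rows t*n_beads .. t*n_beads + n_beads - 1). Modified in place conceptually;
// the recorded output holds the labeled beads only, with dimensions
// (n_frames, n_labeled * n_traj, 2) flattened column-major.
//
// Uses R's RNG (norm_rand) so results are reproducible under set.seed().

// [[Rcpp::export]]
NumericVector rouse_bd_cpp(NumericMatrix state, int n_traj, int n_beads,
                           double k_s, double D, double h,
                           int tether_bead, NumericVector anchor, double k_t,
                           double burn_time, int n_frames, int sub_per_frame) {
  const int nrow = n_traj * n_beads;
  std::vector<double> x(nrow), y(nrow), fx(nrow), fy(nrow);
  for (int i = 0; i < nrow; ++i) { x[i] = state(i, 0); y[i] = state(i, 1); }

  const double noise = std::sqrt(2.0 * D * h);
  const double mob = D * h;
  const long n_burn = (long)std::ceil(burn_time / h);
  const long n_rec = (long)(n_frames - 1) * sub_per_frame + 1;
  NumericVector out((R_xlen_t)n_frames * nrow * 2);

  for (long step = -n_burn; step < n_rec; ++step) {
    // record at frame boundaries (frame 0 is the state right after burn-in)
    if (step >= 0 && step % sub_per_frame == 0) {
      long f = step / sub_per_frame;
      for (int i = 0; i < nrow; ++i) {
        out[f + (R_xlen_t)n_frames * i] = x[i];
        out[f + (R_xlen_t)n_frames * (nrow + i)] = y[i];
      }
    }
    // forces
    for (int t = 0; t < n_traj; ++t) {
      const int off = t * n_beads;
      for (int j = 0; j < n_beads; ++j) {
        double fxi = 0.0, fyi = 0.0;
        if (j > 0) {
          fxi += k_s * (x[off + j - 1] - x[off + j]);
          fyi += k_s * (y[off + j - 1] - y[off + j]);
        }
        if (j < n_beads - 1) {
          fxi += k_s * (x[off + j + 1] - x[off + j]);
          fyi += k_s * (y[off + j + 1] - y[off + j]);
        }
        if (j == tether_bead) {
          fxi += k_t * (anchor[0] - x[off + j]);
          fyi += k_t * (anchor[1] - y[off + j]);
        }
        fx[off + j] = fxi;
        fy[off + j] = fyi;
      }
    }
    // update
    for (int i = 0; i < nrow; ++i) {
      x[i] += mob * fx[i] + noise * norm_rand();
      y[i] += mob * fy[i] + noise * norm_rand();
    }
    if (step % 1000 == 0) {
      for (int i = 0; i < nrow; ++i) {
        if (!std::isfinite(x[i]) || !std::isfinite(y[i]) ||
            std::fabs(x[i]) > 1e6 || std::fabs(y[i]) > 1e6) {
          stop("Rouse integration diverged; use a smaller substep");
        }
      }
    }
  }
  out.attr("dim") = IntegerVector::create(n_frames, nrow, 2);
  return out;
}
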