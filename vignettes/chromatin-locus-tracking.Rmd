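---
title: "Analysing chromatin locus trajectories: dynamics, mechanics, compaction and radiality"
author: "chromotrace"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Analysing chromatin locus trajectories}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chromotrace)
```

# Scope

Live-cell tracking of fluorescently labeled genomic loci produces, per cell,
a short 2D trajectory for each labeled locus (typically ~120 frames over
~80 s) plus a nuclear outline. From these, chromatin organisation is read
out at four levels:

* **dynamics** — mean square displacement (MSD), the anomalous-diffusion
  exponent, the short-time effective diffusion constant and the gyration
  radius of each trajectory;
* **mechanics** — the effective spring constant confining each locus, and a
  Rouse-polymer tethering model that splits it into chain stiffness and a
  tether to a nuclear landmark;
* **compaction** — the scaling exponent relating mean spatial distance of
  locus pairs to their genomic distance;
* **radiality** — the normalized nuclear radial distance of each locus and
  its relation to mobility.

Because public trajectory data for this kind of experiment are scarce, the
package carries simulators (confined beads, Rouse chains, fractional
Brownian motion, synthetic nuclei and pair distances) that generate inputs
with the statistical structure the estimators assume. Every estimator is
validated against the generators' ground truth in the test suite; the same
experiments are re-run from scratch by `scripts/acceptance.R`.

# Trajectory model and dynamics

A trajectory is a sequence $p(t)$ sampled at a fixed frame interval
$\Delta t$. The time-averaged MSD at lag $k\Delta t$ averages over all
start frames (overlapping windows),

$$\mathrm{MSD}(k\Delta t) = \left\langle\, |p((m+k)\Delta t) - p(m\Delta t)|^2 \,\right\rangle_m,$$

and the ensemble-averaged MSD is the unweighted mean of the member
time-averaged curves at each lag, over the trajectories that reach that
lag. MSD curves are fitted with the anomalous-diffusion power law

$$\mathrm{MSD}(t) = 4 D_\mathrm{app}\, t^{\beta},$$

by ordinary least squares of $\ln \mathrm{MSD}$ on $\ln t$. The default fit
range is the first quarter of the available lags (common single-particle
tracking practice; long lags are noisy and, for time-averaged curves, based
on few displacement pairs); the range used is recorded in every fit object.
Chromatin loci are subdiffusive, with $\beta$ typically between 0.35 and
0.46.

Two deliberate numerical choices:

* **Short-time diffusion constant.** `estimate_deff()` regresses the
  time-averaged MSD on lag time *through the origin* over the first 4 lags
  and divides the slope by 4. Four lags (~2.7 s at the default frame
  interval) balance bias (MSD curvature from confinement) against variance;
  the lag count is configurable and recorded. With only the first lag the
  estimator becomes $\mathrm{MSD}(\Delta t)/(4\Delta t)$, which is the
  right companion for spring-constant estimation on strongly subdiffusive
  data (see below).
* **Localization noise floor.** Independent per-frame localization error of
  s.d. $\sigma$ per axis adds a flat $4\sigma^2$ to every MSD value.
  `fit_msd_power_law(..., with_offset = TRUE)` fits
  $4 D_\mathrm{app} t^\beta + 4\sigma^2$ with $\sigma^2 \ge 0$ constrained
  (Levenberg–Marquardt, initialized from the log–log fit). This recovers
  $\sigma$ reliably when the underlying motion is close to free diffusion;
  for strongly confined loci the fit is *degenerate* — a small $\beta$
  mimics a flat floor — and a short-lag linear fit (slope $4D$, intercept
  $4\sigma^2$) is the more robust probe, at the cost of a slight upward
  bias from confinement curvature. The analysis drivers demonstrate both.

The gyration (trajectory) radius,
$R_g = \sqrt{\langle |p - p_C|^2 \rangle}$ with $p_C$ the trajectory
centroid, measures the explored territory; $R_g^2$ is the "locus
territory". Localization precision of the instrument itself is estimated
from immobilized-bead recordings as the spread of repeated localizations
(`estimate_localization_precision()`).

# Langevin mechanics and the spring–territory law

On short time scales a confined locus follows an overdamped Langevin
equation with a harmonic restoring force $-k_\mathrm{eff}(p - p_C)$ and
friction $\gamma = k_BT/D_\mathrm{eff}$ (Einstein relation). All energies
are expressed in units of $k_BT$, so spring constants carry
$k_BT\,\mu m^{-2}$ and no absolute temperature appears anywhere.

`estimate_keff()` regresses the step $p((m{+}1)\Delta t) - p(m\Delta t)$ on
the centroid-relative position $p(m\Delta t) - p_C$, pooling x and y
components, with the slope fitted through the origin. To first order the
slope is $s = -k_\mathrm{eff} D_\mathrm{eff} \Delta t$, giving the default
mapping $k_\mathrm{eff} = -s/(D_\mathrm{eff}\Delta t)$; the `"exact"`
option inverts the full Ornstein–Uhlenbeck decay factor,
$k_\mathrm{eff} = -\ln(1+s)/(D_\mathrm{eff}\Delta t)$, removing the
first-order bias (about 10% once $\Delta t$ reaches a fifth of the
relaxation time). Per-axis slopes are reported as diagnostics; trajectories
with negative raw $k_\mathrm{eff}$ are flagged and excluded from group
means but counted in QC summaries.

Three properties of this estimator matter in practice:

* **Finite-length artifact.** The regression uses the *sample* centroid, so
  even free Brownian motion yields a slightly negative slope (order
  $-3/n$ for $n$ frames), and confined trajectories acquire a positive
  $k_\mathrm{eff}$ inflation of order $\tau/T$, where $\tau$ is the
  relaxation time and $T$ the trajectory duration. At $T = 40\tau$ we
  measure about +10%; at $T = 120\tau$ about +4%. Validation experiments
  therefore use trajectories spanning $\gtrsim 100\tau$.
* **Stationary identity.** For any stationary trajectory the combination of
  the regression slope with a *single-lag* $D_\mathrm{eff}$ reduces
  algebraically to $k_\mathrm{eff} = k_BT/\mathrm{Var}$ per axis — the
  equipartition identity — regardless of whether the motion is Markovian.
  With the default 4-lag $D_\mathrm{eff}$ the estimate instead acquires a
  timescale factor when the motion is anomalous at the sampling scale
  (measured ~1.8× on bead-chain trajectories). When comparing against
  equilibrium polymer models, use `deff = estimate_deff(traj, n_lags = 1)`.
* **Territory law.** Equipartition, $k\,\mathrm{Var} = k_BT$ per axis with
  $\mathrm{Var} = R_g^2/2$ in 2D at long $T$, predicts
  $\langle k_\mathrm{eff}\rangle = a\,\langle R_g^2\rangle^{-b}$ with
  $a = 2$, $b = 1$. `spring_territory_sweep()` verifies this end to end on
  confined-bead simulations over $k \in \{25, ..., 400\}\,k_BT\mu m^{-2}$
  (4000 frames at $\Delta t = 0.02\,\tau$; measured $a \approx 2.07$,
  $b \approx 1.00$ — the small excess on $a$ is the finite-length artifact
  above).

# Rouse tethering inversion

To separate chain elasticity from attachment to nuclear landmarks, the
locus is modelled as a bead on a Rouse chain with one locus at genomic
position $c_t$ tethered (spring constant $k_t$) to a fixed point. The
chain segment of genomic length $\Delta c_{it} = |c_i - c_t|$ acts as a
spring of stiffness $K_R/\Delta c_{it}$ in series with the tether:

$$k_{\mathrm{eff},i} = \frac{k_t K_R}{K_R + \Delta c_{it} k_t}
  \quad\Longleftrightarrow\quad
  \frac{1}{k_{\mathrm{eff},i}} = \frac{1}{k_t} + \frac{\Delta c_{it}}{K_R}.$$

`infer_tether()` inverts measured $(c_i, k_{\mathrm{eff},i})$ by ordinary
least squares of $1/k_\mathrm{eff}$ on $\Delta c$: $K_R = 1/\mathrm{slope}$
and $k_t = 1/\mathrm{intercept}$. With exactly two loci this reproduces the
closed two-locus formula
$K_R = (\Delta c_1 - \Delta c_2) k_1 k_2 / (k_2 - k_1)$ identically, and
`predict_keff_tethered()` followed by `infer_tether()` is an exact round
trip (property-tested over random admissible parameters). Conventions and
caveats:

* $K_R$ carries per-genomic-distance units ($k_BT\,\mu m^{-2}\,$Mb) so the
  series formula is dimensionally consistent; reports that quote a chain
  spring constant in plain $k_BT\,\mu m^{-2}$ implicitly fix a
  $\Delta c$ scale.
* With two loci and an unknown tether position the system
  $(K_R, k_t, c_t)$ is under-determined, so $c_t$ is a **required input**,
  and it must lie outside the genomic span of the measured loci (all chain
  segments must point towards one tether) unless explicitly overridden.
* A negative fitted slope or intercept means no positive spring pair can
  reproduce the measurements; the solution is returned but flagged
  infeasible.

The simulation cross-check (`test-mechanics`, and re-run by the acceptance
script) integrates a 16-bead chain (1 Mb per bond) with its end bead
tethered, measures $k_\mathrm{eff}$ at three labeled beads by step
regression with the single-lag $D_\mathrm{eff}$, and inverts. Sampling uses
one slowest-mode relaxation time per frame — computed exactly as the
smallest positive eigenvalue of the harmonic stiffness matrix, because for
an end-tethered chain the slow collective mode is several times slower
than the free-chain estimate, and under-sized burn-in or frame spacing
shows up directly as bias in $k_\mathrm{eff}$. Recovered $K_R$ and $k_t$
land within ~10–15% of the generator values at 30 chains × 60 frames.

# Compaction and variation decomposition

For locus pairs at genomic distance $s$, the mean spatial distance follows
$\langle R\rangle \propto s^{\delta}$; smaller $\delta$ means tighter
packing. The averaging rule is time-average first, then cell average:
$\langle R\rangle = \langle\langle R(t)\rangle_t\rangle_\mathrm{cell}$,
with the time average taken over the first 30 frames by default
(configurable). `fit_compaction()` fits $\delta$ by log–log least squares
and supports nested genomic spans, since compaction is compared across
scales (e.g. within ~5 Mb vs across ~30 Mb).

Distance variability splits into two sources: the spread of per-cell time
means $\langle R\rangle_t$ across cells (cell-to-cell variation) and the
within-cell fluctuation $\delta R(t) = |R(t) - \langle R\rangle_t|$
(temporal variation). For additive Gaussian jitter of s.d. $\sigma_t$ the
mean absolute deviation converges to $\sigma_t\sqrt{2/\pi}$ (half-normal
mean), which `decompose_variation()` inverts as `implied_temporal_sd`. The
matching generator, `generate_pair_distances()`, draws a per-cell mean
(power law plus truncated Gaussian cell offset) and Gaussian frame jitter,
and the round trip recovers both s.d. components within 15% at 200 cells.

# Nuclear radiality

The normalized radial distance of a locus is $\mathrm{NRD} = d/\rho$: the
distance $d$ from the nuclear centroid to the locus, divided by the
distance $\rho$ from the centroid to the nuclear boundary **along the same
ray** (not the nearest-boundary distance — the two coincide only for
circles). For elliptical boundaries the ray intersection is solved in
closed form; for polygons, segment by segment, taking the furthest
intersection so mildly non-convex outlines still span the full nucleus.
Segmentation jitter can place a locus marginally outside its nucleus: raw
values in $(1, 1.05]$ are clipped to 1 and flagged, larger values are an
error. A 256-gon approximation of an ellipse agrees with the closed form
to $10^{-3}$.

`simulate_nucleus()` places loci at exact target NRDs, and
`correlate_mobility_position()` reports the Pearson correlation between
NRD and $D_\mathrm{eff}$ with the descriptive classes used for such data
($|r| < 0.2$ negligible, $0.2$–$0.4$ weak). No preferred-position mode
estimator is provided; histograms and empirical CDFs are exported and mode
calling is left to the user.

# The simulators and what they do (not) emulate

* `simulate_ou()` uses the **exact discrete OU transition** (decay
  $e^{-\Delta t/\tau}$, stationary variance $k_BT/k$ per axis, initial
  state drawn stationary), so it has no integration error and serves as
  the analytic oracle for the spring estimator.
* `simulate_fbm()` draws fractional Gaussian increments from their exact
  covariance (Cholesky factorization; Hurst index $\beta/2$), scaled so
  the ensemble MSD is $4 D_\mathrm{app} t^\beta$; $\beta = 1$ reduces to
  Brownian motion.
* `simulate_rouse_chain()` integrates overdamped Brownian dynamics
  (Euler–Maruyama, compiled) with substep
  $h \le 0.01\,k_BT/(D\,k_\mathrm{max})$, equilibrium-drawn initial bonds
  and a burn-in of ten slowest-mode relaxation times (exact eigenvalue).
  Tether anchors are fixed points in the lab frame, reflecting the
  nuclear-landmark interpretation.
* `add_localization_noise()` adds i.i.d. Gaussian localization error;
  `simulate_nucleus()` and `generate_pair_distances()` provide geometry
  and pair-distance inputs as described above.

Default "experiment-like" settings are 120 frames at
$\Delta t = 0.667$ s, $\sigma_\mathrm{loc} = 0.05\,\mu m$, $D$ a few
$10^{-3}\,\mu m^2 s^{-1}$, $R_g$ of 0.09–0.15 $\mu m$ — the scale of
interphase chromatin loci — so pipeline smoke tests resemble real data.
All generators consume R's RNG in a documented order and are
bit-reproducible under a fixed seed.

What the generators deliberately do **not** emulate: viscoelastic memory
beyond fBm (no generalized Langevin kernel), crosslinked or loop-extruding
polymers, excluded volume and hydrodynamic interactions, 3D motion
(analysis is 2D as imaged), motion blur within an exposure, and
segmentation errors beyond the small-NRD-overshoot case. Passing tests
therefore show the estimators are correct *for the assumed statistical
structure*; on real data the usual caveats of model mismatch apply.

# Group statistics

Welch's unequal-variance t test (two-tailed, Welch–Satterthwaite degrees
of freedom) and the classical one-way ANOVA F test are implemented as
explicit closed forms so the pipeline's numerical surface is directly
testable; the test suite cross-checks them to machine precision against
their standard R counterparts and to Monte-Carlo accuracy against
permutation oracles, and verifies a type-I error of 0.05 ± 0.01 under the
null. Significance labels follow the star convention `ns` ($p > 0.05$),
`*` ($p < 0.05$), `**` ($p < 0.005$), `***` ($p < 0.0005$). No
multiple-testing correction is applied; pairwise comparisons are emitted
uncorrected and labelled as such.

# Design choices on open points

* Nuclear-motion calibration subtracts the **per-frame** centroid by
  default (a single-reference-frame mode is available) — per-frame
  subtraction is the stronger drift correction and matches how centroid
  series are produced by segmentation.
* The step-size regression pools x and y (doubling the sample); per-axis
  slopes are kept as diagnostics since the pooling convention is not
  standardized in the literature.
* Trajectories with missing frames are rejected, never interpolated:
  interpolation autocorrelates steps and biases both MSD and the spring
  regression.
* Condition labels (cell-cycle stage, transcription-inhibitor treatment)
  are grouping metadata, not code paths: every analysis runs identically
  within each group.

# Problem sizes

The validation experiments run at sizes chosen to keep each estimator's
sampling error a few times smaller than the tolerance it is tested at:
500 trajectories for free-diffusion recovery; 200 × 120 frames for the
subdiffusion exponent; 100 × 6000 frames for spring-constant recovery
(long trajectories keep the centroid artifact ~5%); 5 spring constants ×
100 trajectories × 4000 frames for the territory law; 16 chains of 32
beads for Gaussian-chain scaling; 30 chains × 60 frames for tether
inversion; 40 cells per pair for compaction and 200 for the variation
decomposition; $10^4$ replicates for test calibration.

# Limitations

The estimators are 2D and assume complete, uniformly sampled trajectories.
$D_\mathrm{eff}$ is a windowed secant estimator, not a model-based MLE; its
value depends (documented, configurable) on the lag window. The spring
constant inherits the finite-length inflation discussed above, and on
strongly subdiffusive data its interpretation is timescale-bound. The
tether inversion assumes a single tether outside the measured span and
exact knowledge of $c_t$. Compaction fits treat the per-span pair sets as
independent; no error-in-variables correction is applied to the log–log
regressions.
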