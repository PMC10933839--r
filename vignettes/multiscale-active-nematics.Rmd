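---
title: "From motor kinetics to active-nematic hydrodynamics: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From motor kinetics to active-nematic hydrodynamics: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(actonem)
```

`actonem` links three scales of a cytoskeletal active nematic — an actin
film driven by synthetic multi-headed myosin clusters — in one computable
chain: stochastic single-cluster kinetics, a scaling map to hydrodynamic
parameters, and continuum active-nematic flow, plus the flow-field
statistics used to characterize such materials and synthetic-data
generators that let every stage be tested without microscopy data.

## 1. The motor-cluster stepping model

Each enzymatic head cycles irreversibly through three states: (1) unbound
with ATP, (2) bound post-powerstroke with ADP, (3) bound and nucleotide
free (rigor). Hydrolysis-plus-binding proceeds at `k12`, ADP release at
`k23`, and ATP uptake-plus-unbinding at `k31_per_atp * [ATP]` — linear in
ATP, so low ATP traps heads in rigor and raises the duty ratio. Heads are
independent; a cluster of valency *n* is *n* copies of the cycle evolved
jointly by the exact Gillespie algorithm (`gillespie_trajectory()`).

Geometry enters through the anchor position *x(t)* of the multimerization
domain, maintained per filament as the rearmost bound head plus *s*/2. A
binding head lands at `Normal(x + s/2, sd = s/2)`; the second parameter is
read as a standard deviation (reading it as a variance would give the
distribution units of length^1/2). The step length *s* defaults to
0.036 µm, the actin pseudo-helical repeat; since every length in the model
is proportional to *s*, the rate calibration absorbs this choice.

Outputs:

* **single filament** — velocity (total anchor displacement over total
  simulated time, unbound gaps included) and run length (anchor travel per
  maximal interval with ≥ 1 head bound; a run still open at `t_max`
  contributes its distance so far);
* **two filaments** — crosslink probability `P_cl` (time-weighted fraction
  with both filaments occupied) and sliding strain rate `epsilon`.
  Filaments are treated as antiparallel and unbounded; anchor jumps of both
  filaments add to the relative sliding. An event contributes strain when
  the cluster is crosslinked immediately before *or* immediately after the
  transition, so the anchor jump of the crosslink-establishing binding
  counts as sliding. Under the stricter before-only reading (available as
  `strain_establish = FALSE`) the strain rate genuinely declines a few
  percent above ~300 µM ATP because re-established crosslinks discard
  their first advance; the inclusive reading keeps `epsilon` strictly
  increasing in ATP, which is the structure the scaling analysis assumes.

Because heads are independent and pick filaments uniformly, the stationary
crosslink probability has the closed form
`1 − 2(1 − p/2)^n + (1 − p)^n` with the renewal bound fraction
`p = (1/k23 + 1/k31) / (1/k12 + 1/k23 + 1/k31)`. The test suite holds the
simulator to this oracle to within Monte-Carlo error, alongside
Kolmogorov–Smirnov checks of every holding-time distribution and an
independent R replay of the C++ event bookkeeping.

### Calibration and its limits

`calibrate_rates()` scans a log-spaced grid (12 points per rate over
`[0.1, 10^3]` 1/s for `k12`, `k23` and `[10^-3, 10]` 1/(s·µM) for
`k31_per_atp`), scoring each triple by the summed squared log-error of
simulated tetramer velocity and run length against the measured endpoints
(0.5 µm/s & 4 µm at 10 µM; 10 µm/s & 0.5 µm at 500 µM).
`calibrate_motor_rates()` adds a local refinement pass around the coarse
winner. The loss is log-scaled so a factor-two miss on a 0.5 µm/s target
weighs the same as on a 10 µm/s one.

The four endpoints jointly over-constrain this model. The required 20×
velocity ratio forces the unbinding time to dominate the 10 µM cycle,
which drives the low-ATP duty ratio toward one and makes low-ATP runs far
longer than 4 µm; conversely, parameters that shorten those runs cannot
slow the 10 µM velocity enough. The attainable run-length ratio grows
faster than the velocity ratio everywhere we probed, so the best
compromise leaves residuals of roughly 40–115% on individual endpoints
(reported by the calibration object and flagged `within_tol = FALSE`).
Every downstream conclusion uses only the qualitative ATP structure of
the kinetics — `epsilon` rising, `P_cl` falling, both shifting with
valency — which is robust across the near-optimal region of the scan.

## 2. The hydrodynamic scaling model

Active nematic turbulence is governed by one length,
`ell = sqrt(K / alpha)`, from balancing elastic stress `K / ell^2` against
the active stress `alpha`, and by the dissipation-limited speed
`v = ell * alpha / eta = sqrt(K * alpha) / eta`. The package maps
microscopic curves to these observables pointwise over the ATP grid
(`predict_curves()`):

* activity `alpha = alpha0 * epsilon_hat^beta`, with the strain rate first
  normalized to its curve maximum (`epsilon_hat`), exponent default
  `beta = 0.1`;
* elasticity `K = K0 + kappa * c_e` with effective crosslinker
  concentration `c_e = c_m * P_cl + c_p`; defaults `K0 = 0.001`,
  `kappa = 10 K0`, `c_m = 1`, `c_p = 0`.

All proportionality constants are unity (`alpha0 = eta = 1`) and outputs
carry normalized companions, so predictions are shape statements — peak
positions and monotonicities — not dimensional ones. The competition is
transparent: rising ATP raises strain (activity up) but releases
crosslinks (elasticity down), and their product `K * alpha` can peak at
intermediate ATP. `find_speed_peak()` reports the grid argmax plus the
stationarity residual `|K' alpha + K alpha'|` (central differences in
`log10 [ATP]` on unit-normalized curves; below `1e-3` on refined grids at
genuine interior peaks), a boundary flag, and `K'` at the peak. Stiffer
crosslinks (larger `kappa`) move the peak to lower ATP; higher valency or
added passive crosslinker moves it higher; at `beta = 1` activity growth
dominates for strongly rising strain-rate inputs and the peak disappears.

A Michaelis–Menten alternative (`mm_microscopic_curves()`) replaces the
simulated curves with closed forms — saturating motor speed
(`km_v = 50` µM), crosslink probability decaying from 1 to a 0.05 floor
(`km_p = 50` µM), `epsilon = v_m * P_cl` — chosen to peak inside the
1–1000 µM window; it reproduces the same qualitative structure and
provides deterministic fixtures for the test suite.

Stochastic curves are used raw by default. `smooth_microscopic_curves()`
offers optional spline smoothing (df = 5 in `log10 [ATP]`, the smallest
basis that reproduces the deterministic backbone without displacing its
peak; isotonic projection keeps `P_cl` decreasing) for peak localization
on noisy curves, where it lifts one-grid-step recovery at 5%
multiplicative noise from roughly half the replicates to ≥ 90%.

## 3. Flow-field statistics

`flow_analysis` functions consume velocity-field time series (arrays plus
pixel size and frame interval; delimited-text I/O with a JSON sidecar).

* `flow_speed()` returns both conventions in use: `v_mean = Σ|u_i|/N` and
  `v_rms = sqrt(mean |u|^2)`; `v_rms ≥ v_mean` always (Jensen).
* `velocity_correlation_length()` radially bins the direction
  autocorrelation `C_uu(r)` (unit vectors, FFT correlation, periodic
  wrap) and interpolates the first crossing of 1/e.
* `vortex_length()` implements correlated displacement velocimetry: the
  mean-subtracted vorticity field is cross-correlated with the velocity
  field, the vector response is projected on the azimuthal direction
  `z × r_hat`, azimuthally averaged in 1-px bins, and the radius of the
  single maximum (parabolic sub-bin refinement) is returned.
* `frame_set_variability()` applies any estimator to consecutive
  non-overlapping frame sets (5 × 5 by default) and returns the
  across-set standard deviation — the error-bar convention for these
  statistics.

Two numerical points deserve emphasis. First, vorticity is differentiated
from the same velocity data it is correlated with, so uncorrelated
measurement noise produces a spurious response at 1-px displacement; the
peak search therefore starts at 2 px, matching the generator's `R ≥ 2 px`
domain. Second, the correlation radius is *not* the core radius: evaluated
on analytic profiles (dense continuum integral, computed independently in
the test oracle), the azimuthal response of an isolated Rankine vortex
peaks at 1.29–1.31× the solid core radius, and a Lamb–Oseen vortex at
1.59× its Gaussian core scale — the finite vorticity patch smears the
correlation outward. The estimator is therefore validated as a *scale*
measurement: across radii 5–20 px and noise to 10% of peak speed it tracks
the continuum correlation radius to within a few percent and scales
linearly with the generator radius and pixel size. Interpreted as a core
radius it would read ~30% high on these profiles; on experimental
turbulent flows the analogous constant depends on the vortex profile.

## 4. The lattice-Boltzmann active-nematic solver

The continuum stage is a hybrid solver: a D2Q9 BGK lattice-Boltzmann
update for momentum (Guo forcing, periodic boundaries, `dx = dt = 1`)
coupled to a finite-difference Beris–Edwards update for the nematic
tensor. Q is the three-dimensional traceless tensor restricted to
in-plane directors (Q_xz = Q_yz = 0 is invariant under in-plane flow);
the stored components are Q_xx, Q_xy, Q_yy. The bulk free energy

    f = (A0/2)(1 − U/3) Tr Q² − (A0 U/3) Tr Q³ + (A0 U/4) (Tr Q²)²

has, for uniaxial `Q = q (nn − I/3)`, the ordered minimum
`q* = 1/4 + (3/4) sqrt(1 − 8/(3U))` — at the working coupling `U = 3.5`,
`q* = 0.616 ≈ 0.62`, and `equilibrium_order()` is verified against direct
numerical minimization of the implemented `lb_bulk_free_energy()`. A
strictly two-dimensional traceless Q would lose the cubic invariant and
could not reproduce this value, which fixes the convention. One-constant
elasticity `(K/2)|∇Q|²` yields the molecular field `H`; the stress
assembles the flow-alignment terms (ξ), the antisymmetric part `QH − HQ`,
the Ericksen term `−K ∂Q:∂Q`, and the active stress `−alpha Q` (positive
`alpha` extensile).

Working parameters follow the production set: `tau = 1.5` (viscosity
`(tau − 1/2)/3 = 1/3` in lattice units), `xi = 0.7`, `Gamma = 0.13`,
`A0 = 0.1`, `U = 3.5`; `K` and `alpha` are the experiment knobs.
Verification anchors: the uniform ordered state is a machine-precision
fixed point; mass is conserved to relative 1e-10 and net momentum to
1e-6 per 1000 steps; a seeded shear wave decays at the analytic BGK rate
within 5%; a perturbed passive nematic relaxes back to `q*` within 1e-3.

Runs here use a reduced 64 × 64 lattice with a 5000-step burn-in and 5000
sampled steps (every 50th), initialized from i.i.d. Gaussian director
perturbations of 0.1 rad; larger lattices and longer runs are a
configuration change, not a code path. At `alpha = 0.01` this setting
sustains active turbulence, and the time-averaged kinetic energy
*increases* with `K` across 0.002–0.05 (Spearman ρ = 1 over 3 seeds per
K in the shipped analysis) — elasticity governs how efficiently motor
stress becomes flow. Closing the loop, `vortex_length()` applied to
simulated LB velocity fields gives a turbulent length that falls with
activity at fixed `K`, consistent with `ell ~ sqrt(K/alpha)`.

## 5. Synthetic data: what it does and does not emulate

`synth_vortex_field()` builds steady vortex flows of known geometry —
Rankine (solid-body core, 1/r tail; maximum speed exactly at the core
radius) or Lamb–Oseen — singly or tiled in alternating-sign lattices,
with i.i.d. Gaussian velocity noise per frame. `synth_microscopic_curves()`
produces Michaelis–Menten backbones with multiplicative log-normal noise.
These fixtures have known ground truth, which real data never offers: the
generator emulates the *structure* the estimators assume (vortical flow of
one scale; monotone rate curves) but not optical-flow artifacts, spatially
correlated noise, vortex-size polydispersity, or drift. Passing tests
therefore demonstrate estimator correctness and noise robustness at the
stated levels, not performance on raw microscopy.

## 6. Problem sizes, seeds, degenerate inputs

Shipped analyses and tests use: calibration scans of 12³ + 7³ points at
2–6 trajectories × 30–60 s each; ATP sweeps of 20 points × 30 replicates
× 50 s; oracle-equivalence runs of 8 × 600 s; 96² flow fields with 5–25
frames; LB lattices of 32²–64² for 10³–10⁴ steps. All randomness flows
from explicit integer seeds through one documented child-seed scheme
(`derive_seeds()`), and equal seeds give bit-identical results on every
stochastic entry point. Degenerate inputs are defined, not excluded:
`t_max = 0` yields an empty trajectory; `[ATP] = 0` is the rigor limit
(absorbing bound states, `p = 1`); zero activity flags `ell` infinite;
a uniform translation field has no vortex radius and errors; curves that
never cross 1/e return the maximum radius with a flag.

## Known limitations

* The stepping model omits inter-head coupling, load-dependent rates,
  correlated binding, filament ends and bending — deliberately, as in the
  model it implements; its printed motility endpoints cannot all be met
  at once (section 1), so calibration reports its residuals rather than
  hiding them.
* The scaling map is a proportionality argument: outputs are normalized
  shapes, and `K`'s linearity in crosslinker concentration is an ansatz.
* The LB solver fixes one elastic constant and two dimensions, and its
  reduced default lattice resolves the turbulent cascade only a decade
  below the box size.
* The vortex-radius estimator measures the correlation radius, a
  profile-dependent multiple (~1.3× for solid cores) of the geometric
  core radius.
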