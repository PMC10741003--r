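---
title: "A nested state-space method for myocardial current-density estimation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A nested state-space method for myocardial current-density estimation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(mcgss)
```

## The estimation problem

Magnetocardiography records the heart's magnetic field at `Ns` magnetometer
channels; the sources are per-voxel current densities `j(n)` (3 components
per voxel, `3 Nv` states). The forward map `z(n) = H j(n)` is linear and
known (Biot–Savart superposition over voxels), but with `Ns << 3 Nv` the
inversion is badly ill-posed: the minimum-norm pseudoinverse reproduces the
measurements essentially exactly while scattering current into physically
meaningless patterns (`pseudoinverse_baseline()` demonstrates this on the
shipped study). `mcgss` instead constrains the inversion with an
electrophysiological state-space model and estimates both the states
(current densities) and the model parameters (propagation structure) from
the data. The clinically motivating question is localization of electrically
silent — potentially arrhythmogenic — tissue.

## Model and procedure

**Propagation model.** Activation travels between 26-neighboring voxels
through first-order Thiran all-pass filters. A connection with group delay
`tau` (samples) stores the integer part `k = floor(tau)` and coefficient
`a = (1 - frac(tau)) / (1 + frac(tau))`, realizing
`H(z) = z^-k (a + z^-1) / (1 + a z^-1)`; the filter has unit magnitude
response everywhere and group delay `k + (1-a)/(1+a) = tau` for
`f <= fs/10` (property-tested to 2%). Each connection carries a 3x3 gain
block mapping the delayed source-voxel current components into the target
voxel; the nine gains share one coefficient `a`. The per-voxel output is
`j_v(n) = sum_o C_(v,o) y_(v,o)(n) + b_v u(n)`, with the scalar control
waveform `u(n)` injected at the sinoatrial node.

**Control function.** `u(n)` is the discrete derivative of a normalized
action-potential template (tanh upstroke, plateau, exponential
repolarization), scaled to peak at 1. The algorithm relies only on this
normalization; the template's exact ionic provenance is immaterial. The
default upstroke width is 3 ms: together with the fixed measurement gain of
70 this calibrates the simulated R-peak to ~90 pT, the amplitude regime of
real MCG recordings (and the operating point the study's evaluation
quantities refer to). Plateau (200 ms) and repolarization constant (100 ms)
are ordinary human ventricular values; the repolarization contribution to
`u` is ~2% of the depolarization spike, so the QRS-like deflection
dominates the field.

**Initialization.** Six voxel types with conduction velocities 1.1 m/s
(sinoatrial node, atrium, ventricle), 0.012 m/s (AV node) and 4.5 m/s
(His-Purkinje); pathological tissue is non-conducting and never connected.
Delays are `tau = ||p_i - p_o|| / phi(type_i) * fs` — the *receiving*
voxel's velocity, so a wavefront slows down when entering slower tissue —
clamped at 1 sample (Thiran validity; the clamp only engages for
His-Purkinje tissue at coarse sampling rates and is logged). A wavefront
sweep from the sinoatrial root assigns each reachable voxel one parent,
an activation time, a unit-L1 current direction along the last propagation
step, and the gain block `c_jk = delta_i,j * sign(delta_o,k)`. Ties
(several parents reaching a voxel at the same iteration time) resolve to
the lowest parent index; the whole construction is deterministic and is
cross-checked in the tests against an independent event-queue
implementation. Connection slots allowed by tissue compatibility but not
used by the wavefront keep their delays and zero gains — the refinement
step can grow them, which is how alternative propagation routes are
learned.

**State estimation.** A Kalman filter over the `3 Nv` states. The
covariance is stored and propagated only on the neighbor support (state
pairs whose voxels are 26-neighbors or identical); the innovation
covariance `S` (`Ns x Ns`) is factorized densely. The gain matrix is used
as the one-step covariance transition, and all-pass delay lines are fed
with the corrected estimates so measurement information propagates into
future predictions (a configuration flag selects predicted estimates
instead). On toy systems whose support mask is complete the sparse filter
agrees with a dense textbook implementation to machine precision (tested).

**Refinement.** Per epoch, a forward pass feeds the all-pass bank with the
filtered trajectory and accumulates analytic gradients of
`L = Lm + gamma Lv` over all time steps: `Lm` the mean squared measurement
residual, `Lv` the squared positive excess of any voxel's L1 current over
1.01 (currents may fall below the nominal maximum — partial tissue
filling — but have no reason to exceed it). Gains update by plain
full-batch gradient descent; all-pass coefficients use the exact
sensitivity recursion `dy/da(n) = (x(n-k) - y(n-1)) - a * dy/da(n-1)`
(validated against central finite differences to 1e-4 relative; the
`Lv` term deliberately contributes nothing to the `a` gradients). After
the update, coefficients wrap back into `[0, 1]` by trading fractional
against integer delay, repeating as often as needed; at `k = 0` the
coefficient clamps at 1. Self-connection slots exist in the parameter
layout but are frozen at zero gain by default: a trainable one-sample
self-feedback loop turns the network into an adaptive IIR integrator whose
gradient descent destabilizes at any practical learning rate
(`refinement_config(update_self = TRUE)` re-enables them).

**Nested loop.** State estimation and model refinement alternate for a
fixed number of epochs; a final filter run under the refined model yields
the estimates that are evaluated. Activity maps (per-voxel max L1 over the
cycle), threshold segmentation (below threshold = pathological) and
DICE/recall/precision with a 0.6-1.0 sweep at step 0.01 complete the
pipeline.

## The simulated validation study

The `"full"` profile reproduces the reference conditions: a 26 x 37 x 1
sheet of 2.5 mm voxels (962 voxels, 2886 states) as an unrolled heart
surface — atria on top, one-voxel AV block, T-shaped His-Purkinje tree with
an apical branch row, ventricles below — simulated for 1 s at 2000 Hz;
144 magnetometer channels (4 x 4 x 3 tri-axial sites over
250 x 250 x 100 mm, centered 200 mm above the sheet); measurement gain 70;
white sensor noise of 40 fT/sqrt(Hz) equivalent noise spectral density
(per-sample sigma = ensd * sqrt(fs/2) = 1.26 pT — white noise fills the
Nyquist band). The ground truth contains a 35-voxel non-conducting patch in
the right ventricle; the initial model assumes a healthy heart. Layout
shapes are parameterized fractions of the sheet, so the same layout renders
at any resolution.

What the generator emulates: morphologically plausible sinus-rhythm
activation order and timing, uniform normalized activity in healthy tissue,
realistic field amplitudes and sensor noise, and a silent region whose
field deficit (~20 pT at peak) must be detected. What it does not emulate:
secondary/return currents, torso conductivity, sensor transfer functions
and finite pickup areas, refractory-period gradients, beat-to-beat
variability, and respiration/motion. Passing tests therefore demonstrate
algorithmic correctness and detectability under idealized single-beat
conditions, not clinical performance.

## Problem sizes used by the test suite

The full nested optimization at reference scale takes on the order of an
hour. The package's automated tests validate the complete pipeline on the
same study rendered small — the `"reduced"` profile: a 10 x 14 sheet
(140 voxels, 6-voxel patch) for 0.45 s at 1000 Hz, with the 4 x 4
tri-axial sensor plane scaled and moved closer by the sheet's scale factor
so the angular size of the patch relative to the array matches the
reference geometry (shrinking the heart under a fixed 200 mm array would
collapse the conditioning of the inverse problem), and a 25-epoch
refinement budget at learning rate 0.03. The short budget doubles as
early-stopping regularization: on this small, ill-posed instance prolonged
descent drifts toward measurement-equivalent but diffuse solutions. The
profile is a single-realization study (one fixed noise seed, like the
reference conditions); with a 6-voxel patch, single-voxel
misclassifications move the DICE score by about 0.1 between noise
realizations. Forward-model quantities (R-peak amplitude, truth-vs-initial
difference) are always computed at the full 962-voxel scale, where they
take seconds.

## Numerical choices and degenerate inputs

* Delays below 1 sample clamp to 1 (warning); `tau >= 1` is required at
  initialization and preserved by the wrap rules.
* `sign(0) = 0` in the gain rule, so propagation steps orthogonal to the
  parent's current direction receive zero gain.
* The covariance recursion symmetrizes after every predict and correct and
  floors the diagonal at zero; off-support entries produced by
  `(I - KH) P` are discarded (projection), which keeps the filter O(support)
  but — like any covariance truncation — is not guaranteed
  positive-semidefinite; with the default noise settings this is benign
  (tested for nonnegative diagonals).
* A singular innovation covariance raises an error naming the smallest
  eigenvalue; parameter updates abort on non-finite gradients or coefficient
  excursions beyond |a| > 1e6 rather than silently wrapping garbage.
* All voxel indexing is 1-based (R convention), x fastest, then y, then z;
  state `3(v-1)+c` is component `c` of voxel `v`.
* Filter memories and delay lines are zero at n = 0 (diastole); all passes
  are strictly causal (inputs up to n-1 only), so open-loop simulation,
  filtering, and the refinement forward pass share identical semantics.

## Design choices on genuinely open points

* **All-pass realization.** The recursion
  `y(n) = a (x(n-k) - y(n-1)) + x(n-k-1)` realizes DC group delay
  `k + (1-a)/(1+a) = tau` exactly, which is the property the delay
  initialization relies on; an alternative convention with one extra
  sample of input delay is selectable (`convention = "printed"`) and
  shifts every hop by one sample (tested).
* **Sensitivity recursion.** The implemented `dy/da` recursion is the
  exact derivative of the realized filter (including the dependence
  through `y(n-1)`); it is the variant that passes finite-difference
  validation.
* **Units.** Geometry in mm (SI conversion inside the forward model);
  measurements in pT throughout the estimation pipeline; current densities
  in the control-normalized unit with the forward model treating unit
  amplitude as 1 A/m^2 — one fully active 15.6 mm^3 voxel then produces
  ~2.7 pT at 200 mm under gain 70, placing the simulated R-peak in the
  empirically observed ~100 pT range. A literal A/mm^2 reading (available
  via `current_unit = "A/mm^2"`, factor 1e6) would put single-voxel fields
  six orders of magnitude above physiological MCG amplitudes.
* **Kalman noise parameters** (`q_diag`, `r_diag`, `p0_diag`) are genuinely
  free: `r_diag` defaults to the known per-sample sensor noise variance;
  `q_diag` and `p0_diag` are config keys. The filter's correction strength
  (q/r ratio) controls how much measurement structure enters the estimates
  and hence how sharply the refinement gradients localize; the defaults
  were chosen so the shipped study profiles converge stably.
* **Evaluation set**: all voxels (no ventricle-only restriction), ties at
  the threshold classify healthy, sweep ties resolve to the lowest
  threshold.

## Known limitations

Single-layer geometry only in the shipped study (the code takes any
`(nx, ny, nz)`); no smoothing (forward filter only); no adaptive noise
estimation or hyperparameter search; full-batch gradient descent without
momentum or schedules; covariance support fixed to the 26-neighborhood. The
refinement landscape is non-convex and ill-posed — measurement-equivalent
models exist that dim tissue diffusely rather than locally; the
propagation-model bias, the constraint loss, and the filter's data
injection are what steer the descent toward localized solutions, and with
unfavorable hyperparameters (very weak filtering, oversized learning
rates) the loop can converge to diffuse minima or diverge. The defaults
avoid both on the shipped profiles.
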