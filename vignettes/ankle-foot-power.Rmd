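---
title: "Ankle–foot power during walking: model, conventions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ankle–foot power during walking: model, conventions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The mechanical model

The package treats the distal lower limb as two rigid segments, foot and
shank, observed through reflective markers (nominally 150 Hz) and a force
platform (nominally 300 Hz) during the stance phase of a single walking
pass. All quantities live in one right-handed laboratory frame with Z
vertical up and positions in metres; the convention is declared once and
never inferred from data, because axis conventions are the single most
common source of silent sign errors in this kind of pipeline.

Three power series are computed over stance:

* **Ankle power (six degrees of freedom).**
  `P_ankle = F_ankle · ΔV_ankle + M_ankle · ω_ankle`. The translational
  term uses the difference between the two ankle-point velocities: the
  velocity of the material point of the shank coinciding with the ankle
  centre, `v_com(shank) + ω_shank × (r_ankle − r_com(shank))`, minus the
  same expression for the foot. The rotational term uses
  `ω_ankle = ω_shank − ω_foot`. Including the translational term matters:
  a joint modelled with all six degrees of freedom can transmit power
  through force times relative translation even when the net moment is
  small.
* **Foot power (deformable-segment view of everything distal to the
  ankle).** `P_foot = GRF · [V_cm + ω_foot × R_cop/cm] + M_free · ω_foot`,
  with `R_cop/cm = r_cop − r_com(foot)`. This is the rate of work done by
  the ground on the foot-fixed material point at the centre of pressure,
  plus the free-moment contribution.
* **Total.** `P_sum = P_ankle + P_foot`, enforced as an exact samplewise
  identity in the container class.

`F_ankle` and `M_ankle` come from Newton–Euler inverse dynamics of the
foot: `F_ankle = m a_com − m g − GRF`, and the Euler equation about the
foot COM solved for the ankle couple, with the segment inertia tensor
rotated into the lab frame at every sample. The loads are defined as those
applied **by the shank on the foot**; the package pins this convention with
an energy-balance identity rather than by documentation alone: for a rigid
foot, the sum of all external powers (ankle force at the ankle point, ankle
couple, GRF at the COP material point, free moment, gravity) must equal the
time derivative of the segment's kinetic energy. `energy_balance_residual()`
evaluates this residual with the pipeline's own numerical derivatives, and
the test suite requires it to stay below 1% of peak power on noiseless
synthetic trials. Any sign error in any term breaks this identity, which is
why it is the package's primary mechanical self-check.

### Outcome features

Per stance, nine scalars: peak `P_ankle` and `P_sum` (maxima inside the
propulsion window) and the foot's absorption peak (the magnitude of the
`P_foot` minimum in that window, reported positive so that faster walking
increases all peak features monotonically — the signed series is always
retained); plus positive and negative work (trapezoidal integrals of the
positive/negative parts) of all three series over the full stance. For the
foot this equals integrating over its absorption (`P_foot < 0`) and
generation (`P_foot > 0`) sub-intervals, which is how the package
operationalizes the foot absorption phase: the published definitions of
heel-pad/soft-tissue absorption phases are not reproducible from summary
descriptions, so the package uses the sign of `P_foot` itself, a declared
and testable choice. The propulsion window runs from the last upward zero
crossing of `P_sum` to toe off, falling back (with a warning) to the final
50% of stance for series that never cross zero; an identically zero series
is a degenerate-input error. Features are computed per trial and averaged
across a subject's trials within a speed condition; the default minimum of
3 trials per cell reflects synthetic-study economics, while laboratory
protocols typically require 6 representative trials (the parameter is
exposed).

## Preprocessing parameters

| Parameter | Default | Units | Why |
|---|---|---|---|
| marker filter cutoff | 10 | Hz | standard for walking kinematics; removes soft-tissue and tracking jitter |
| force filter cutoff | 50 | Hz | preserves the fast force transients that matter for power timing |
| filter order | 2 (per pass) | — | 2nd-order Butterworth run forward–backward: zero phase lag, 4th-order effective magnitude |
| event threshold | 50 | N | conventional vertical-GRF contact threshold |
| plausible stance | 0.3–1.5 | s | brackets observed stance times (~0.54–0.79 s across slow to fast walking) |
| normalization grid | 101 | points | 0–100% stance in 1% steps for ensemble curves |

Numerical choices worth knowing:

* **Zero-lag filtering.** Filtering forward and backward removes phase
  distortion (essential: a lagged GRF against an unlagged velocity biases
  power), at the price of squaring the magnitude response — the single-pass
  half-power point becomes a quarter-power point. Edge transients are
  suppressed by odd-reflection padding whose length is computed from the
  slowest pole of the designed filter (long enough for the zero-state
  transient to decay below double precision), not a fixed constant.
* **Clocks.** Forces are filtered at their native 300 Hz (so the 50 Hz
  cutoff means what it says) and only then brought onto the marker clock —
  by exact sample picking when the grids nest (300/150 Hz), cubic spline
  otherwise. Gait events are located on the force clock and mapped to the
  nearest marker sample, so stance boundaries are accurate to half a marker
  sample.
* **Derivatives.** Central differences with first-order one-sided ends.
  Angular velocity is extracted from the skew-symmetric part of `Ṙ Rᵀ`;
  angular acceleration differentiates ω (differentiating the rotation
  matrices twice amplifies noise more). The test suite cross-checks the
  rotation-matrix route against an independent quaternion-derivative
  oracle.
* **COP degeneracy.** Below the force threshold the COP is undefined
  (division by a vanishing vertical force); the last valid COP is held and
  the foot-power samples there are forced to zero. Holding, rather than
  emitting NaN, keeps the work integrals finite; zeroing is honest because
  sub-threshold forces contribute negligibly to power.
* **Gaps.** Missing marker samples are an explicit mask. A gap inside the
  stance window rejects the trial with a reason (mirroring manual trial
  selection in laboratory practice); gaps are never interpolated.

## Segment inertia

The study-level literature rarely states its anthropometric source, so the
package pins one explicitly: the adjusted Zatsiorsky segment inertia
parameters (de Leva 1996), shipped as a versioned CSV
(`inst/extdata/anthropometry_deleva.csv`, male and female tables, foot and
shank rows) and recorded in every `inertial_params` object for provenance.
Foot length defaults to 15.2% of stature when no direct measurement is
available. Swapping tables is a one-argument change; the standardized
regression stage is insensitive to the choice because standardization
removes scale.

## The synthetic-data generator

`generate_trial()` emulates one barefoot single-stance pass: foot and shank
COM trajectories as sums of sines (≤ ~1.3 Hz, closed-form velocity and
acceleration), rotations about fixed axes with sinusoidal angles
(closed-form ω and ω̇), a double-hump vertical GRF
(`sin(πs) + 0.3 sin(3πs)`) scaled so its supra-threshold duration equals
the requested stance time (0.63 s default, a typical comfortable-speed
value; peak 750 N ≈ 1.1 body weight for the default 68.4 kg subject), a
smoothstep heel-to-toe COP path, a small sinusoidal free moment, and ≥ 3
markers rigidly attached to each segment, sampled at 150 Hz (markers) and
300 Hz (forces) like the laboratory instruments it stands in for. The
ankle loads are then computed *forward* from the same Newton–Euler
equations the pipeline inverts, making the trial dynamically consistent by
construction; trajectory phases and amplitudes are jittered reproducibly
per seed, and measurement noise is optional and Gaussian.

What it deliberately does **not** emulate: muscle-driven dynamics, impact
transients and soft-tissue (heel-pad) deformation, multi-segment foot
motion, marker soft-tissue artefact, or a swing phase with realistic foot
clearance. Passing tests on this generator therefore demonstrate that the
*computational chain* is correct (filters, poses, derivatives, inverse
dynamics, integrals, model fits), not that the rigid-foot model is an
accurate description of a biological foot — the known overestimation of
foot power by single-rigid-body models applies to any pipeline of this
type.

`generate_feature_table()` inverts the statistical model instead: subject
comfortable speeds drawn per group (defaults 1.23 ± 0.17 and
1.21 ± 0.20 m/s for young and older), slow/fast at ∓30%, features built as
`β₀ + β_S z(speed) + β_A group + β_SA z(speed)·group + intercept + noise`
with σ_subject = 0.3 and σ_ε = 0.4 by default. Its `confound` mode draws
the groups at 1.37 ± 0.09 vs 1.05 ± 0.13 m/s with a truly null age effect,
the configuration in which an age-only model shows a spurious age
difference that an added speed term removes.

## Statistical conventions

* Features and Speed are standardized (sample SD, n − 1 denominator) so
  slopes read as effect sizes; AgeGroup is coded young = 0 / older = 1.
  When a response is already on the model scale (simulation output),
  `standardize_response = FALSE` skips the response transform — otherwise
  the rescaling by the total outcome SD would make true coefficients
  unrecoverable.
* Two-step fitting: ML for LLF/AIC (comparable across fixed-effect
  specifications), REML for coefficient estimates. CIs use the asymptotic
  normal approximation on the REML standard errors; p-values use a t
  reference with residual degrees of freedom (a z-test is available via
  `ddf = "normal"`). These are the common reporting conventions; more
  elaborate degrees-of-freedom corrections change p-values marginally and
  slopes not at all. Monte-Carlo calibration in the acceptance suite puts
  the realized 95% CI coverage at roughly 0.93–0.95 at 40 subjects — the
  mild anticonservatism expected of normal-approximation intervals for
  between-subject terms.
* Fixed-effects R² is the squared Pearson correlation between the observed
  response and the fixed-effects-only prediction.
* A fit that converges with zero random-intercept variance is flagged
  (`singular`), not raised: on noiseless or near-noiseless synthetic data
  this is the expected outcome, and its coefficient estimates remain valid.
  On fully degenerate (zero-residual) data the coefficient covariance is
  not estimable and is reported as NA.
* No multiple-testing correction is applied across the nine features; the
  ladder mirrors the single-feature reporting convention of the study
  design it implements, and users combining many features should correct
  downstream.
* The subset confound analysis standardizes within the analyzed subset
  (the alternative — freezing the full-sample transform — changes the
  scale but not the significance pattern) and takes ⌈N/2⌉ subjects per
  half, ranking by comfortable speed.
* The continuous-age robustness variant substitutes standardized age for
  the binary group in the same ladder.

## Problem sizes used by the tests

The suite favours fixed-seed Monte-Carlo checks sized for tight
determinism: 20 noiseless trials for the energy-balance and
inverse-dynamics criteria; a 3 × 3 grid of (β_S, β_A) ∈ {0, 0.4, 0.8}²
with 200 replicates per cell (40 subjects × 3 speeds each) for estimator
bias and CI coverage; 100 replicates for the confounding demonstration and
null-calibration properties. `scripts/acceptance.R` re-runs the same
computations from a user-supplied seed (100 replicates per grid cell) and
writes every quantity it computes; nothing in the report is hard-coded.

## Known limitations

* Single rigid foot segment; no multi-segment or deformable foot model.
* Overground single-stance segmentation only — no treadmill (multi-contact)
  streams, no gap filling or marker-swap repair.
* The laboratory-dataset benchmark requires the corresponding deposited
  dataset to be downloaded and converted to the documented `features.csv`
  layout; the package ships no copy of it, so that comparison cannot run
  offline.
* The generator's smooth trajectories make numerical differentiation
  benign; real marker noise at impact is harsher than anything the
  synthetic tests exercise.
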