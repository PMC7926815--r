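---
title: "Estimating vertical ground reaction force and gait timing from a torso-mounted sensor"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating vertical ground reaction force and gait timing from a torso-mounted sensor}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gaitgrf)
```

## The problem

Vertical ground reaction force (vGRF) — the vertical force the ground exerts
on each foot — and the timing quantities derived from it (ground contact
time, touch-down and toe-off events, double-support and flight phases,
stance impulse) are the bread and butter of gait analysis. They are measured
directly with force plates, instrumented treadmills, or pressure insoles;
none of these travels well. A single inertial/GPS unit strapped to the torso
does, and its acceleration, angular-rate, speed and vertical-motion channels
carry enough information to estimate those quantities indirectly, provided a
model has once been trained against a force reference such as instrumented
insoles.

`gaitgrf` implements that estimation chain end to end:

1. a **synthetic gait generator** producing paired torso-sensor and insole
   streams with exact ground truth,
2. **session handling**: clock synchronization between the two recorders via
   calibration jumps, and stride segmentation from the sensor stream alone,
3. **per-stride features** (27 summary statistics of the sensor channels)
   and **target parameters** (12 insole-derived quantities),
4. **correlation-based feature selection** in two stages,
5. **bagged regression trees** predicting each retained target per stride,
6. **K-nearest-neighbor curve synthesis** reconstructing the full vGRF curve
   of each stride from its predicted time parameters, and
7. a **sequence-to-point LSTM** predicting per-sample vGRF and binary
   ground-contact labels directly from the raw 6-channel sensor stream.

Because the recorded datasets such a chain is normally trained on are not
shipped with the package, the generator in (1) is a first-class module: every
later stage is developed and tested against it.

## The synthetic gait model

### Force templates

One stride is one full gait cycle of the left foot (left touch-down to the
next left touch-down). Within a stride, each foot produces force only during
its stance interval of length $t_c$ (the ground contact time). Forces are
expressed in multiples of body weight (BW); newtons are recovered by
multiplying with $m g$, $g = 9.81\,\mathrm{m/s^2}$.

* **Walking** uses the classic double-peaked "M" profile: half-cosine
  segments through the knots $0 \to p_1 \to v \to p_2 \to 0$ placed at
  quarter points of stance. It has exactly two local maxima ($p_1$, $p_2$, the
  loading and push-off peaks), one interior minimum (the mid-stance valley
  $v$, default $0.55\,p$), and is continuously differentiable.
* **Running** uses a single-peak inverted-"V" bump,
  $p \cdot \sin(\pi u)^{1.5}$ over normalized stance time $u \in [0,1]$.

Peak amplitudes are drawn per stride from the physiological bands
1.0–1.5 BW (walking) and 2.0–2.9 BW (running), increasing with speed within
each band plus a small stride-to-stride jitter (SD 0.03 BW).

### Impulse balance fixes the duty factor

Averaged over a steady stride, the total vertical force on the body must
equal body weight — otherwise the runner would drift up or down. With two
feet phase-shifted by half a stride, each foot must therefore satisfy

$$\frac{1}{T}\int_0^{T} f(t)\,dt = \tfrac12 \;\text{BW},$$

where $T$ is the stride duration. For the walking template the stance mean
is $(p_1 + p_2 + v)/4$ exactly (each half-cosine segment averages its
endpoint midpoint), so the generator solves

$$t_c^{\text{walk}} = \frac{2T}{p_1 + p_2 + v}, \qquad
  t_c^{\text{run}} = \frac{T}{2\,\mu\,p}, \quad \mu = \int_0^1 \sin(\pi u)^{1.5} du \approx 0.556.$$

This single constraint produces the defining kinematic dichotomy
automatically: over the whole walking peak band the duty factor
$t_c/T$ stays above 0.5 (both feet overlap — double support), and over the
whole running band it stays below 0.5 (neither foot on the ground — flight).
The exponent 1.5 in the running bump is deliberate: a plain raised cosine
(stance mean $p/2$) would make the 2.0 BW lower band edge degenerate with a
duty factor of exactly 0.5 and zero flight time.

### Torso kinematics

The estimation methods only require that sensor-derived features correlate
with the targets; the torso model is therefore phenomenological:

* vertical displacement per stride: $z = A(1 - \cos 4\pi t/T)$ — two bounces
  per stride, one per step, with amplitude $A$ around 2–3 cm in walking and
  5–7 cm in running. Vertical velocity and acceleration are obtained by
  *discrete* differentiation, so displacement is exactly the double integral
  of (vertical acceleration − g) and the three channels are mutually
  consistent by construction;
* mediolateral sway (lateral acceleration, roll rate) oscillates at the
  *full-stride* period with a sign-definite value at left touch-down — this
  is what lets the segmenter tell left from right steps;
* forward acceleration, yaw/pitch rates, speed ripple and heading wobble
  oscillate at the step period with speed-dependent amplitudes.

Every oscillation amplitude carries log-normal stride-to-stride jitter
(≈28% CV, in line with reported torso-acceleration variability) and a random
second-harmonic admixture. This is not decoration: without independent
variability all amplitude features collapse onto speed (pairwise |r| > 0.9),
and the correlation-based selector would be left with nothing to choose
from. With it, the default sessions yield a stable selected set that always
contains mean speed and stride duration. Stride durations follow a
piecewise-linear decrease with speed (steep across walking speeds, flat in
running, ≈4% residual SD), calibrated so the default walk-dominated session
composition has a mean stride duration of about 1.04 s.

### The insole measurement model

The reference instrument is imperfect in two specific ways, both emulated:

* **quantization**: pressures resolve at 1.0 N/cm²; with an effective sensor
  area (default 5 cm², a config value) this maps to a force step;
* **swing artifact**: during the *second half* of each swing interval — when
  the foot travels back toward the ground and presses against the insole — a
  spurious positive force of bounded magnitude (default ≤ 0.1 BW) appears.
  The first half of the swing stays exactly zero.

The artifact matters downstream: insole-derived touch-downs can fire early
on artifact bumps, and force references are nonzero where the true vGRF is
zero, so error metrics computed against insoles overestimate the true error
of an estimator that correctly predicts zero flight force.

### What the generator does not emulate

No musculoskeletal dynamics, no landing-style variation (heel versus
forefoot strike changes the curve shape in real data), no GPS error, no
soft-tissue or mounting resonances, and Gaussian white sensor noise only.
Tests passing on this generator demonstrate the *mechanics* of the chain —
correct segmentation, unbiased target extraction, models that recover
planted structure, curve synthesis that reproduces held-out strides — not
performance on real recordings.

## Segmentation and synchronization

Stride boundaries are left touch-downs, detected as prominent peaks of the
20 Hz low-passed vertical acceleration, gated to moving intervals (speed
above 0.3 m/s) and to samples where the low-passed lateral sway is positive,
refined to the nearest vertical-velocity zero crossing, with a 0.4 s minimum
spacing. In this synthetic world the torso is at its lowest point at
touch-down, so the refinement crossing is upward; the detector accepts the
nearest crossing of either sign. The detector is a standard inertial
gait-event heuristic and is validated only against the generator's truth
(median boundary error 0 ms; occasional 10–20 ms misses at the gait onset
and at walk-to-run transitions).

Clock synchronization uses the calibration jumps recorded at both ends of a
session: a jump is a sharp co-occurring spike in insole total force
(threshold 3 BW) and torso vertical velocity (threshold 1.2 m/s). Spike
times are refined by parabolic interpolation; the leading pair gives the
offset and the leading/trailing pairs give a linear drift estimate. The
tolerance of one insole sample period (20 ms) has no external reference
value; it is what the jump sharpness supports.

## Features and targets

The 27 per-stride input features are fixed in one canonical table
(`feature_names()`): mean, peak-to-peak range (p-p) and standard deviation
of the seven channels {speed, forward/lateral/vertical acceleration,
vertical velocity, vertical displacement, ground track}, plus stride
duration, step length, cadence, maximum speed, minimum vertical displacement
and absolute heading change. Range variants precede SD variants in the
canonical order; orientation-dependent 3D-angle and body-frame angular-rate
statistics are deliberately excluded. Step length is mean speed × step time
by default (a path-integral variant is available; the two agree except for
quadrature).

The 12 targets per stride are the touch-down and toe-off times, contact
times, peak forces and stance impulses of both feet, plus flight time and
double-support time. Touch-down is the first rising crossing of the contact
threshold (default 2% of body weight) and toe-off the first falling
crossing, both linearly interpolated and reported relative to the stride
start. With strides anchored at *left* touch-downs, the right foot's stance
straddles the boundary in walking, so within a stride its toe-off (ending
the stance carried over from the previous stride) *precedes* its touch-down;
contact time is therefore defined as the total within-stride contact
measure, which equals TO − TD whenever a stance lies contiguously inside the
stride (always for the left foot, and for the right foot in running).
Multi-edge measures inherit the threshold-crossing delay (≈13 ms per edge at
2% BW): single events stay within one insole sample of truth, contact times
within about two, double support within about four. Normalized force
variants divide by body weight in newtons.

## Feature selection

Two greedy stages with Pearson correlations:

1. any feature pair with $|r| > 0.9$ loses its later-listed member (so SD
   variants yield to their p-p siblings, and cadence to stride duration);
2. features whose $|r| \le 0.3$ against **every** target are dropped, then
   targets with $|r| \le 0.3$ against every surviving feature are dropped.

The strict/non-strict inequalities follow the rule as stated; the greedy
canonical-order tie-break is this package's documented choice (a clustering
formulation would be equally defensible). Constant columns correlate as 0
with a warning. Both stages are idempotent and invariant to row order, and
on tables with planted structure (informative + redundant + noise columns)
the pipeline recovers exactly the informative set.

## Per-stride parameter models

One bagged ensemble of regression trees per target: 30 learners, bootstrap
resampling with replacement at bag fraction 1, minimum leaf size 8, all
features available at every split (pure bagging, not a random forest), and
the prediction is the plain mean of the learners. Three input modes:
the selected features (`six_optimal`), their first six principal components
(`pca6`, computed on standardized inputs), or all 27 (`all27`). The
right-foot toe-off time is excluded from modeling (it correlates weakly with
every input); flight and double-support time are modeled like the other
targets, giving 11 fitted models by default.

Peak forces and impulses are divided by body weight in newtons before
fitting and multiplied by the *query* subject's weight at prediction, which
is what lets a model trained on one subject produce sensible forces for
another. BW is interpreted as weight (mass × g); the linearity is exact by
construction.

The error metric is NRMSE = 100 · RMSE / mean(reference). The mean
normalizer is an inference, fixed by the worked correspondence that at a
reference mean of 2.5 BW an NRMSE of 2.7% equals 0.0675 BW of absolute
error; a range normalizer is available but off by default.

## KNN curve synthesis

Training strides are stored per foot as body-weight-normalized curves
resampled onto a common 0–100% stride grid (101 points). The key vectors are
purely temporal: (stride duration, TOL, GCTL) for the left foot and (stride
duration, GCTR) for the right — the left touch-down is omitted because it
predicts poorly, the right toe-off because it was dropped as a target, and
peak vGRF because it lives on a different scale than seconds. Queries use
raw Euclidean distance (all key components share units; no standardization),
average the K = 8 nearest curves pointwise on the normalized grid — whether
averaging should happen on absolute or normalized time is genuinely open;
normalized-time averaging is this package's choice — and the result is
warped to the predicted duration and rescaled by the query subject's weight.
Results vary by well under 2 NRMSE points for K anywhere in 5–12.

The accelerated search is a small kd-tree with (distance, index)
lexicographic tie-breaking; exhaustive search is the in-package oracle and
the two agree exactly, by test. KNN synthesis can only reproduce force
patterns present in its library — that restriction is inherent to the
method, not an implementation limit.

## The LSTM curve models

Two sequence-to-point regressors share one architecture: LSTM → additive
zero-mean Gaussian input noise (training only) → LSTM → dropout (training
only) → dense 2-unit head. The vGRF model ends in ReLU with MSE loss; the
contact-label model in a sigmoid with binary cross-entropy; both use adam.
Inputs are the six raw channels (3D acceleration, 3D angular rate) min-max
scaled per channel to [−1, 1] — per-channel because accelerations and
angular rates have incommensurate units; inference reuses the training
statistics. Ground speed, vertical velocity and orientation are excluded as
inputs.

The stream is cut into windows of 400 samples (one mean stride at 400 Hz)
shifted by one sample; the target of a window is the value at its final
sample, so a trace of length $n$ yields exactly $n - 399$ predictions and
none for the first 399 samples. Contact probabilities binarize at 0.5
(values ≥ 0.5 become 1).

The backend is implemented natively in R with batched matrix operations and
hand-derived backpropagation-through-time; the test suite checks the
analytic gradients against numerical differentiation to ~1e-4 relative
error. Defaults are hidden sizes 64/64, dropout 0.2, noise SD 0.05, batch
256 — layer order is what matters; performance is robust to the neuron
count. Window length and sampling rate are reducible through the
configuration; the test and acceptance runs use the desk-scale setting
(100 Hz, 100-sample windows, hidden sizes 24/24, 150 training strides, 5
epochs for the label model and 10 for the force model, which converges more
slowly),
where held-out contact-label accuracy exceeds 85% and the ReLU head pins
>90% of true swing samples to exactly zero force — the scaled-down analogue
of the headline behaviour at full rate. A notable property carries over: the
network predicts *zero* force whenever the foot is airborne, while the
insole reference shows the swing artifact, so insole-referenced NRMSE is an
upper bound on the true error.

## Numerical choices and degenerate inputs

* Half-open, 0-based sample indexing everywhere in stride tables (CSV-facing).
* Gravity 9.81 m/s²; BW conversions always via mass × g.
* A stationary trace segments into an empty stride table (not an error);
  a foot that never crosses the contact threshold yields contact time 0 and
  NA event times with a warning (not an error).
* Zero-contact strides are excluded from curve libraries with a warning;
  K is clamped to the library size with a warning.
* Constant channels scale to 0 in the LSTM scaler; constant columns
  correlate as 0 in the selector.
* Transition strides (walk→run) truncate the carried-over right stance at
  the boundary, so the mode dichotomy (double support only in walking,
  flight only in running) holds for every stride; impulse balance is exact
  for steady strides and approximate across transitions.
* Problem sizes in the shipped tests: sessions of 40–200 strides for
  mechanics checks, 1500 strides for parameter recovery, 150 training
  strides at 100 Hz for the LSTM — sizes at which every behaviour under
  test is already stable.

## Known limitations

The synthetic validation shows internal consistency, not field accuracy; on
real recordings the segmentation heuristic, the 2% contact threshold and the
insole artifact model would all need verification against the actual
instruments. Antero-posterior and medio-lateral force components are out of
scope (the insole reference measures only the vertical component), as are
speed-dependent bias corrections and landing-style modeling. The KNN route
cannot generalize to unseen curve shapes; the LSTM route can, but its
real-data accuracy depends on training data this package does not ship.
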