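---
title: "Sparse inertial motion reconstruction: models, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sparse inertial motion reconstruction: models, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sparsekin)
```

## The problem

Five body-worn inertial measurement units — two wrists, two ankles, one
torso — observe only the distal ends of the kinematic chain.  The joints
that matter most for posture, the shoulders and hips, carry no sensor.  A
single instantaneous wrist orientation is compatible with a continuum of
elbow-swivel and shoulder configurations, so the inverse kinematics problem
is ill-posed frame by frame.  `sparsekin` resolves the ambiguity the way a
human observer does: by looking at the history.  A two-second window of all
five sensor streams is regressed onto the current kinematic state of the
four uninstrumented proximal segments (left/right upper arm, left/right
upper leg).

A second, subtler failure mode is *kinematic bleed-through*: a regressor
trained only on natural daily-living motion learns the strong statistical
coupling between distal and proximal motion, and then hallucinates shoulder
activity whenever the wrist shakes — even when the shoulder is pinned.  The
package addresses this with dedicated *hard-negative* training material:
distal-isolation movements (locked-humerus elbow flexion, constrained
pronation/supination, seated knee extension) in which every proximal joint
is verifiably still (angular speed strictly below 0.1 rad/s), mixed into
every training batch at a fixed ratio (10% by default).

## Representations

All orientations are unit quaternions, scalar-first `(w, x, y, z)`, Hamilton
convention; `q1 %q% q2` applies `q2` first.  Raw sensor quaternions undergo
two calibration steps: a limb-class basis permutation from the sensor's ENU
frame into the Y-up world frame (`coord_permute`), and a T-pose boresight
alignment (`boresight_calibrate`) that left-multiplies by the inverse of the
orientation captured at the calibration instant, so every stream starts at
the identity and mounting offsets cancel exactly.

The prediction target is deliberately not the full proximal orientation.
The relative rotation across each limb, `q_rel = q_proximal %q%
q_distal^-1`, is factored into a *twist* about the limb's long anatomical
axis and a residual *swing* that re-points the limb
(`swing_twist_decompose`).  Only the swing is predicted: axial twist is the
component wrist-worn sensors measure worst, and it does not move the limb's
endpoint.  Per-joint twist axes default to the T-pose limb directions — the
horizontal x axis for the arms and the vertical y axis for the legs
(`twist_axes_default`).  A single fixed x axis for all four joints would
classify knee articulation as twist and strip it from the leg targets;
the per-joint choice keeps the decomposition anatomically meaningful, and it
is what makes endpoint positions a pure function of the swing during
evaluation.

Each frame contributes a 50-dimensional feature vector: five sensors times
(quaternion 4, angular velocity 3, linear acceleration 3).  Quaternions are
L2-normalized only; inertial channels are z-normalized per sensor and
modality with one scalar mean and standard deviation pooled across the
three spatial axes (so the direction structure of the 3-vector survives),
then clamped at five standard deviations.  The clamp retains essentially
all Gaussian mass (two-sided tail beyond five sigma is below 1e-6) while
guarding against non-biological transients.  Targets are 40-dimensional:
four joints times (swing 4, angular velocity 3, linear acceleration 3),
with the inertial targets z-normalized by per-joint statistics.

Normalization statistics are always fit on the training partition and
frozen; evaluation and streaming inference reuse them.  Fitting statistics
on a 120-frame inference buffer would make the input distribution depend on
the buffer content and is deliberately not done.

## The regressor

The model is an encoder-only self-attention stack operating as a
sequence-to-vector map: linear embedding 50 to d_model, additive sinusoidal
positional encoding, `n_layers` pre-layer-norm blocks (multi-head
self-attention with residual, then a GELU feed-forward expansion with
residual), a final layer norm, and four parallel per-joint linear heads of
width 10 reading the latent state of the last frame only.  Reading only the
final frame keeps the map strictly causal without attention masking.
Predicted swing blocks are L2-normalized before the loss.  The full-scale
configuration (d_model 256, 6 layers, 8 heads, feed-forward 1024) counts
about 4.76 M trainable parameters, within half a percent of the roughly
4.74 M of the reference architecture it mirrors; the residual discrepancy
reflects embedding/head layout details the reference leaves unspecified,
and the package documents it rather than reverse-engineering an exact
match.

Because no automatic-differentiation framework is part of the package's
dependency footprint, the forward and backward passes are written directly
in matrix code (`model_forward`, `model_backward`) with exact analytic
gradients; the test suite verifies them against central finite differences
at relative tolerance 1e-4 across every parameter kind.  GELU uses the
standard tanh approximation (the forward caches the tanh term for the
backward).  Training uses AdamW (decoupled weight decay 0.01, betas
0.9/0.999).

## The physics-informed objective

The loss is a weighted sum of three terms,
`L = lambda_q * L_quat + lambda_w * L_vel + lambda_a * L_acc`:

* `L_quat = mean(1 - |q_hat . q_gt|)` — a cosine objective on the unit
  sphere, invariant to the antipodal sign ambiguity (`q` and `-q` are one
  rotation).  Sign canonicalization is applied at serialization boundaries
  only, never inside gradients.
* `L_vel`, `L_acc` — Huber (smooth-L1) penalties with knee at 1 on the
  normalized angular-velocity and linear-acceleration targets.  At the knee
  the quadratic and linear branches agree (0.5), and the linear branch is
  used.  The velocity term is what converts hard negatives into gradient
  signal: predicting motion for a pinned shoulder is penalized directly.

Default weights are (1.0, 0.1, 0.01), the critically damped operating
point.  Two readings of the velocity-term scope exist (every batch, or only
hard-negative batches); the package defaults to every batch, which matches
the unconditional composite objective, and exposes
`run_config(vel_scope = "hardneg")` for the restricted reading.  Both loss
terms operate on normalized targets — the same space the head predicts in.

## Post-processing

Raw frame-by-frame predictions can violate physiology and carry jitter.
Two repairs run in order:

1. **Joint-limit clamping** (`clamp_joint_limits`): hinge joints (elbow,
   knee) clamp the signed twist angle about the hinge axis to [5, 150]
   degrees; ball joints (shoulder, hip) clamp each intrinsic Y-X-Z Euler
   angle to [-45, 150] degrees and re-project onto SO(3).  The same range on
   all three axes is the documented default and the table ships as editable
   JSON.  Euler parameterization is used only transiently; joint frames are
   calibration-aligned so the Y-X-Z singularity sits outside the anatomical
   workspace.
2. **Scalar-gain multiplicative Kalman smoothing** (`mekf_update`): gain
   `K = (P + sigma_p^2) / (P + sigma_p^2 + sigma_m^2)` with process noise
   1e-6 and measurement noise 1e-3; the rotational residual is scaled by
   `K` in the tangent space (log map), re-applied through the exponential
   map, and the estimate renormalized.  Covariance propagation is not part
   of the published filter description; the package uses the standard
   scalar form `P <- (1 - K)(P + sigma_p^2)` with `P0 = sigma_m^2`, which
   converges to the stationary gain implied by constant process noise
   (about 0.031, a time constant of roughly half a second at 60 Hz).

Clamping runs before smoothing: clamping a smoothed trajectory could
re-introduce the very jumps the filter removed.

## Evaluation

All metrics are root-relative, computed in a body-centric frame rooted at
the sternum, so global dead-reckoning drift never contaminates them.
Proximal orientations are reconstructed from the predicted swing composed
with the sensed distal orientation — for ground truth identically — so a
perfect swing prediction scores exactly zero and axial twist (excluded from
the target by design) never enters the comparison.  Endpoint positions come
from a fixed canonical skeleton (humerus 30 cm, forearm 25 cm, thigh and
shank 40 cm, shoulder offset 20 cm, hip offset 10 cm); evaluating both
prediction and truth on one canonical skeleton is the package's form of
skeleton retargeting.  Reported metrics: geodesic mean angular error
(degrees, antipodal-safe), MPJPE (cm), PCK at 5 and 10 cm (strict
threshold), PCK-AUC (exact integral of the PCK curve over 0-15 cm,
normalized so a perfect predictor scores 1), and the temporal smoothness
error (m/s^2) on discrete second derivatives with positions converted to
meters.  Dispersion is frame-wise: joint errors within a frame are
correlated through the chain, so sigma is taken over the per-frame
joint-mean series, not over joint-frame pairs.

## The synthetic kinematic simulator

The generator drives a nine-segment articulated skeleton with
time-parameterized joint-angle channels and derives what real sensors would
measure:

* **ADL-like motion**: each channel is a ramped sum of at most five random
  sinusoids, frequencies drawn from 0.1-1.8 Hz, amplitudes scaled inside
  anatomical ranges.  Within each limb the distal and proximal channels
  share a common harmonic drive (coupling fraction 0.6): natural movement
  is synergistic — elbow flexion co-occurs with shoulder motion, knee
  flexion with hip motion — and it is precisely this synergy that makes
  kinematic bleed-through a real failure mode for a model trained on
  natural motion alone.  Without it, a no-hard-negative model has no
  coupling to unlearn and the hard-negative comparison is vacuous.  Hinge
  channels oscillate around mid-range (70 degrees) so limits hold after
  ramp-in.
* **Hard negatives**: the prescribed distal joint oscillates at 0.5-2 Hz
  while proximal channels carry only micro-wander (0.008 rad at 0.2 Hz,
  angular speed about 0.01 rad/s, an order of magnitude under the 0.1 rad/s
  admissibility threshold).  The seated knee-extension task holds the hips
  at constant 90-degree flexion from the first frame.
* **Sensor synthesis**: orientations compose the segment's world rotation
  with a constant random mounting offset applied as a left-multiplied frame
  offset, which boresight calibration removes exactly; angular velocity is
  the central finite difference of the orientation trajectory through the
  quaternion log (O(dt^2) accurate, verified against analytic derivatives);
  linear acceleration is the discrete second derivative of the sensor
  position.  Acceleration is gravity-free in the world frame by default
  (`sim_config(gravity_mode = "included")` adds the gravity column for the
  alternative convention).  Ground-truth orientations are expressed
  relative to the capture's initial pose — the same frame the calibrated
  input stream lives in — which makes the target-construction round trip
  exact by construction.
* **Channel noise**: i.i.d. Gaussian noise on angular-velocity and
  acceleration channels only.  For stress sweeps the package applies noise
  in normalized-feature units (after z-normalization), because that is the
  space the model consumes; `inject_noise_stream` offers physical units.
  Published noise levels carry no units, so absolute degradation
  percentages are not comparable across conventions — only the qualitative
  shape is.

What the simulator does *not* emulate: soft-tissue artifact, magnetometer
disturbance, sensor bias drift, packet loss, ground contact and balance
constraints, and the long-tailed diversity of real daily-living corpora.
Passing the desk-scale checks therefore demonstrates that the pipeline's
machinery works end to end and that its training signals point the right
way — not that real-world error levels are reproduced.

## Desk-scale study sizes

The built-in study (`desk_study`) is sized for a single CPU: roughly twenty
minutes of synthetic motion (fourteen 60 s ADL captures plus six 30 s
isolation captures for training, two ADL and one isolation capture for
validation), the reduced model (d_model 64, 2 layers, 4 heads, feed-forward
256, dropout disabled at this scale), learning rate 1e-3, batch 64, window
stride 40 frames, six epochs, and two training runs — with and without
hard-negative mixing — evaluated on held-out captures at stride 1.  These
sizes are the package's choice of a reproducible workload; the full-scale
recipe (learning rate 1e-4, 25 epochs, patience 10, dropout 0.1, stride 30)
remains the default `run_config()`.

## Numerical choices and degenerate inputs

* Quaternion normalization rejects zero quaternions; inversion rejects
  near-zero norms (1e-12).
* The log map switches to a series expansion below vector norm 1e-8; the
  exp map likewise — no division by a vanishing angle.
* A raw twist norm below 1e-12 (a pure 180-degree swing orthogonal to the
  axis) returns the identity twist and passes the input through as swing.
* Stream sanitization interpolates NaN runs shorter than 3 frames
  (normalized linear interpolation for quaternions) and rejects files with
  infinities or longer gaps; timestamps must be strictly increasing.
* Batch mixing rounds the hard-negative count half-to-even with a floor of
  one when the ratio is positive, and reshuffles both pools per epoch from
  the run seed; the smaller pool rewinds within an epoch when exhausted.
* All stochastic components (weight init, shuffles, dropout, simulator
  draws) run on private RNG streams derived from explicit seeds and never
  touch the caller's global RNG state.

## Known limitations

Axial twist of the proximal segments is unobservable under this sensor
layout and is excluded from both target and metrics; applications needing
humeral internal rotation would require additional sensing.  The evaluation
skeleton is canonical, not subject-specific.  The pure-R training loop is
sized for the reduced configuration; the full 4.7 M-parameter model trains
correctly but is impractical to fit on one CPU.  Global position is out of
scope by construction: the root is pinned at the sternum.
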