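# sparsekin

Sparse inertial motion reconstruction: estimating the orientations of
**uninstrumented proximal joints** (upper arms and thighs) from only five
body-worn IMUs — two wrists, two ankles, one torso — sampled at 60 Hz.

The package is for biomechanics and human-movement researchers who want a
complete, inspectable implementation of a sparse-IMU inverse-kinematics
pipeline: quaternion frame calibration, swing–twist target
reparameterization, an encoder-only self-attention regressor trained with a
physics-informed multi-task loss and hard-negative batch mixing, anatomical
joint-limit clamping with multiplicative Kalman smoothing, a root-relative
evaluation suite (MAE, MPJPE, PCK, PCK-AUC, TSE), and a synthetic
articulated-kinematics simulator that generates every fixture the pipeline
needs — so the whole system runs end to end on a laptop with no recorded
data.

## The model

With sensors only on the distal segments, the kinematic chain is partially
observable: one wrist orientation maps to a continuum of valid shoulder
configurations.  The reconstruction is therefore posed as sequence-to-vector
regression over a causal window of L = 120 frames (2.0 s):

* **Input** `X ∈ R^{120×50}`: per frame, five sensor blocks
  `[q (4), ω (3), a (3)]`; quaternions L2-normalized, inertial channels
  z-normalized per sensor/modality (one pooled μ, σ across the three axes)
  and clamped at ±5σ.
* **Backbone**: linear embedding → sinusoidal positional encoding →
  pre-layer-norm encoder blocks of multi-head self-attention
  `softmax(QKᵀ/√d_k)V` and a GELU feed-forward expansion → final layer
  norm; four parallel per-joint linear heads read the last frame's latent
  state (40 outputs: per joint a swing quaternion, angular velocity,
  linear acceleration).
* **Target**: the swing component of `q_rel = q_prox ⊗ q_dist⁻¹` after
  removing axial twist about the limb's long axis — the part of the joint
  state that wrist/ankle sensors can actually constrain.
* **Loss**: `L = λ_q (1 − |q̂·q|) + λ_ω Huber(ω̂−ω) + λ_a Huber(â−a)`
  with λ = (1.0, 0.1, 0.01).  The velocity term turns *hard negatives* —
  distal-isolation movements (locked-humerus elbow flexion at 0.5–2 Hz,
  constrained pronation/supination, seated knee extension) with proximal
  angular speed verifiably below 0.1 rad/s, mixed into every batch at 10% —
  into direct gradient pressure against kinematic bleed-through.
* **Post-processing**: per-joint limit clamping (elbow/knee hinge 5–150°,
  shoulder/hip Euler box −45–150°), then scalar-gain multiplicative Kalman
  smoothing `q̂_k = exp(K_k log(q_obs ⊗ q̂_{k−1}⁻¹)) ⊗ q̂_{k−1}` with
  `K_k = (P+σ_p²)/(P+σ_p²+σ_m²)`, σ_p² = 1e−6, σ_m² = 1e−3.

Forward *and backward* passes of the network are implemented directly in
matrix code with exact analytic gradients (finite-difference-verified in
the test suite) and trained with AdamW — no external deep-learning
framework is required.

## Worked example

```r
library(sparsekin)
set.seed(0)

# simulate a locked-humerus elbow-flexion capture and verify admissibility
script <- generate_isolation_task("elbow_flexion", freq = 1.2, seed = 7, duration = 20)
sim <- simulate_imu_stream(script, sim_config(seed = 8, duration = 20))
length(sim$stream$time)                       # 1200 frames at 60 Hz
hard_negative_validity(sim$truth$w)           # TRUE
max(sqrt(rowSums(sim$stream$w[, 1, ]^2)))     # peak distal speed ~ 8.44 rad/s
max(sqrt(apply(sim$truth$w^2, c(1, 2), sum))) # peak proximal speed ~ 0.019 rad/s

# swing-twist decomposition of a mid-capture elbow pose
q_rel <- relative_rotation(sim$truth$q_proximal[600, 1, ], sim$truth$q_distal[600, 1, ])
st <- swing_twist_decompose(q_rel, axis = c(1, 0, 0))
geodesic_error_deg(st$swing, quat_identity())                  # 67.48 deg of swing
geodesic_error_deg(quat_multiply(st$swing, st$twist), q_rel)   # 0 (exact recomposition)

# Kalman smoothing of a noisy static orientation
noisy <- quat_multiply(quat_exp(matrix(rnorm(600, 0, 0.05), 200, 3)),
                       quat_from_axis_angle(c(0, 1, 0), 0.4))
sm <- mekf_smooth(noisy)
```

which prints (orientation error against the true static pose, after
filter convergence):

```
hard-negative admissible: TRUE
peak distal angular speed (rad/s): 8.44
peak proximal angular speed (rad/s): 0.0191
swing angle (deg): 67.48
recomposition error (deg): 0
orientation error, raw -> filtered (deg): 4.37 -> 0.44
```

The isolation capture oscillates the forearm violently while the shoulder
stays still to one-fiftieth of the admissibility threshold; the swing–twist
factorization recomposes the relative rotation exactly; the filter cuts
the orientation noise on a static pose by an order of magnitude.

For the full workflow — corpus generation, training with and without
hard-negative mixing, held-out evaluation — run `desk_study(seed = 42)`
(about 8 minutes on one CPU) or use the CLI in `inst/cli/sparsekin.R`
(`simulate`, `train`, `evaluate`, `infer-stream`, `noise-sweep`).

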