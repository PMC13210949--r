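Package: sparsekin
Title: Sparse Inertial Motion Reconstruction with a Physics-Informed
    Attention Regressor
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Reconstructs the orientations of uninstrumented proximal joints
    (upper arms and thighs) from five body-worn inertial measurement units
    (wrists, ankles, torso) sampled at 60 Hz.  Provides quaternion algebra and
    swing-twist decomposition, T-pose boresight calibration, stream
    sanitization and feature windowing, an encoder-only self-attention
    regressor trained with a physics-informed multi-task loss (quaternion
    cosine, Huber angular-velocity and linear-acceleration penalties), hard
    negative batch mixing against kinematic bleed-through, anatomical
    joint-limit clamping with multiplicative Kalman orientation smoothing,
    root-relative evaluation metrics (geodesic MAE, MPJPE, PCK, PCK-AUC, TSE),
    and a synthetic articulated-kinematics simulator that generates ADL-like
    motion, distal-isolation hard negatives, and noisy IMU streams.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
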