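# gazesim

Simulation and benchmarking of **mobile eye-tracker calibration**: how well
do different function-fitting methods map measured binocular gaze vectors
onto the scene image, under realistic measurement noise and realistic
(often badly distributed) calibration patterns?

A head-mounted tracker measures, per eye, a gaze vector
(φ, θ) — the signed horizontal/vertical angles between the eye's optical
axis and the line from the eyeball centre to the eye camera.  Calibration
fits two regressions from the four features (φ_L, θ_L, φ_R, θ_R) to the
target's image coordinates.  gazesim provides:

* a deterministic 3D scene model (two eyeballs with person-specific κ
  offsets between optical and visual axis, compensated via the
  law-of-sines rotation α = κ − arcsin((r/b)·sin(180° − κ)); eye cameras;
  an equi-angular scene camera; a target plane),
* calibration pattern generators (5/9-point, snake and spiral smooth
  pursuit, 20×20 evaluation grid),
* the three-stage noise model (gaze-direction-dependent systematic error,
  Gaussian precision noise, burst-like false pupil detections),
* five fitting families over their hyperparameter grids — polynomial
  least squares, lasso (sse + αΣ|γ|), ridge (sse + αΣγ²), RANSAC, and
  ε-SVR with linear/poly/rbf kernels,
* the repeated-simulation benchmark protocol: per repetition draw per-eye
  κ ~ N(3.9°, 2.2°) × N(0.2°, 1.7°), simulate + corrupt, fit everything,
  and score the mean angular error on the full-field grid, split inside /
  outside the calibrated area.

## Worked example

```r
library(gazesim)

scene <- scene_config()                      # documented default geometry
calib <- simulate_pattern(pattern_full(), scene,
                          kappa_left  = kappa_pair(hori = 3.9 * pi/180, vert = 0.2 * pi/180),
                          kappa_right = kappa_pair(hori = 3.9 * pi/180, vert = 0.2 * pi/180))
calib <- apply_noise(calib, noise_config(seed = 42))   # default noise mix

fit <- gaze_calib(calib, method = "ridge", degree = 3, alpha = 0.01)
fit
#> Gaze-mapping calibration (ridge)
#>   family = ridge, degree = 3, alpha = 0.01
#>   400 training samples; training RMSE (image fractions): x 0.01294, y 0.01891

test <- simulate_pattern(pattern_grid20(), scene,
                         kappa_pair(3.9*pi/180, 0.2*pi/180),
                         kappa_pair(3.9*pi/180, 0.2*pi/180))
test <- apply_noise(test, noise_config(seed = 43))
mean_angular_error(fit, test, scene)   # 2.536 degrees
image_mse(fit, test)                   # 0.01497 squared image fractions
```

The ridge calibration fitted on a noisy full-field pursuit recovers the
point of regard to ~2.5° when the evaluation gaze vectors carry the same
measurement noise (the noise floor itself contributes most of this; a
grid search over the ridge grid brings the best configuration to ~1.7°).
`run_experiment()` + `summarise_experiment()` automate this over
repetitions, patterns and whole method grids.

A command-line interface covers the same pipeline
(`inst/cli/gazesim simulate | corrupt | fit | evaluate | experiment |
fixtures`); see `?gazesim_cli`.

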