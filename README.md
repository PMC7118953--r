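# mkogait

Marker-based multibody kinematics optimization (MKO) for
three-dimensional canine pelvic limb gait analysis.

Skin-marker motion capture is the standard tool for quantifying dog
gait, but markers ride on skin that slides over the bone (soft tissue
artefact, STA), corrupting joint angles. `mkogait` implements the full
marker-side analysis chain for the right pelvic limb:

* **Model building** from a 15-marker standing calibration: pelvis,
  femur and tibia anatomical frames (x cranial, y proximal, z lateral),
  per-segment marker templates, and hip/stifle joint centres. The hip
  joint centre (HJC) is predicted by per-coordinate linear regressions
  on pelvic width and length plus a greater-trochanter height rule; the
  stifle joint centre (SJC) is the femoral frame origin. Bone-derived
  reference centres come from least-squares sphere (femoral head) and
  cylinder (condyles) fits.
* **Tracking** by two estimators. Single-body optimization (SO) fits
  each segment's template to its measured markers independently — the
  weighted Procrustes problem

  `min_{R,t} sum_i w_i || R p_i + t - q_i ||^2`

  solved in closed form per segment per frame. Multibody kinematics
  optimization (MKO) instead poses the whole limb as a 12-DOF chain
  (6 pelvis DOFs, 3 femur rotations about the HJC, 3 tibia rotations
  about the SJC; spherical joints hold by construction) and minimizes
  the weighted marker misfit globally with Levenberg–Marquardt. Marker
  weights can be uniform, user-supplied, or the reciprocal of each
  marker's local displacement.
* **Analysis**: Cardan z-x-y joint angles (flexion/extension,
  adduction/abduction, internal/external rotation), paw-contact
  detection from the foot marker, 101-point gait-cycle normalization,
  Bland–Altman bias/CI, R², RMSD, and normality-gated paired
  comparisons (Shapiro–Wilk choosing paired t vs Wilcoxon).
* **Synthetic gait**: a seeded simulator of treadmill walking
  (0.7 m/s, 40° stifle flexion range) with a two-component STA model —
  a rigid per-segment artefact that SO cannot correct and per-marker
  non-rigid deformation — plus measurement noise and bone-like point
  clouds, giving every estimator a ground-truthed test surface.

## Worked example

```r
library(mkogait)

# a virtual subject and one default-artefact trial (3 gait cycles, 100 Hz)
subj  <- synthetic_subject(2)
trial <- synthesize_trial(subj$model, generate_gait_script(seed = 2),
                          sta_model("full"), seed = 2)

so  <- so_track(trial$trajectories, subj$model)
mko <- mko_track(trial$trajectories, subj$model)

round(rbind(SO  = trial_rmsd(so,  trial),
            MKO = trial_rmsd(mko, trial)), 2)
#>     hip_fe hip_aa hip_ie stifle_fe stifle_aa stifle_ie
#> SO    2.24   0.74   1.52      2.22      1.23      1.30
#> MKO   0.97   0.98   3.41      1.59      1.92      3.84
```

`trial_rmsd()` is the per-trial RMSD (degrees) between tracked and
ground-truth joint angles over the trial's normalized gait cycles. The
joint constraints cut the flexion/extension error roughly in half
(hip 2.24° → 0.97°) while the out-of-sagittal components do not
improve — internal/external rotation even degrades — the characteristic
behaviour of spherical-joint MKO under soft tissue artefact.

The same pipeline is scriptable from a shell via `inst/cli/mkogait`
(`simulate`, `calibrate`, `track`, `angles`, `evaluate`).

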