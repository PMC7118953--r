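---
title: "Models and methods behind mkogait"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind mkogait}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(mkogait)
```

`mkogait` estimates three-dimensional canine pelvic limb kinematics
from skin markers. This vignette documents the underlying models, the
design decisions taken where the methodology admits several defensible
choices, what the synthetic-data generator does and does not emulate,
and the numerical conventions used throughout.

## The measurement problem

Skin markers do not stay put over the bone. Their motion relative to
the underlying skeleton — the soft tissue artefact (STA) — has two
structurally different parts. A *non-rigid* part deforms the marker
array and can be partially suppressed by rigidly fitting a calibration
template to the measured markers (single-body optimization, SO). A
*rigid* part translates and rotates the whole array together; it is
indistinguishable from true bone motion to any per-segment fit and
passes straight into SO-estimated poses. Multibody kinematics
optimization (MKO) attacks the rigid part by coupling the segments:
with the hip and stifle forced to share joint centres, an artefact that
would move the femur estimate away from its joints must now fight the
marker evidence on the pelvis and tibia as well.

## The multibody model

The limb is three rigid segments — pelvis, femur (thigh), tibia
(crus) — with anatomical frames sharing one convention for a right
limb: x cranial, y proximal, z lateral, right-handed.

* *Pelvis*: origin at the midpoint of the iliac crest markers; x from
  the mid-ischial point to the mid-iliac point; z along the
  left-to-right iliac direction orthogonalized against x.
* *Femur*: origin at the epicondyle midpoint; y towards the greater
  trochanter (GT); z lateral in the plane of origin, GT and lateral
  epicondyle.
* *Tibia*: origin at the malleolus midpoint; y towards the midpoint of
  fibular head and proximal tibial crest; z lateral in the plane
  containing the lateral malleolus.

These axis formulas are this package's concrete reconstruction of the
frame recommendations customary in canine gait work, which are usually
cited rather than printed; they are fixed project-wide and documented
here so results are reproducible from the code alone.

Each segment's markers, expressed once in its frame at the standing
calibration, form its time-invariant *marker template*. Medial markers
(medial epicondyle, medial malleolus) exist only during calibration;
each segment keeps four dynamic markers.

### Joint centres

The stifle joint centre is the femoral frame origin (the epicondyle
midpoint). The hip joint centre is predicted in the pelvic frame: its
x and z coordinates by independent ordinary-least-squares regressions
on pelvic width (iliac crest marker distance) and pelvic length
(mid-iliac to mid-ischial distance) — two predictors, three parameters
per coordinate — and its y coordinate as minus the orthogonal distance
of the GT marker from the *posterior pelvic plane*, implemented as the
total-least-squares plane through the four pelvic landmarks. The
distance enters as a magnitude, so the predicted centre always lies
distal to the plane; this matches the intended geometry whether the GT
sits dorsal or ventral of the landmark plane in a given standing pose.
Whether the "posterior pelvic plane" should instead be a transverse
ischial plane is genuinely open; the four-landmark dorsal plane is the
documented choice and the plane construction is isolated in
`posterior_pelvic_plane()` should a user prefer another.

No published regression coefficients exist for this predictor set, so
the shipped default (`default_hjc_regression()`) is fitted to the
package's own synthetic 24-subject training table and is labelled as
such; real studies should fit `fit_hjc_regression()` to bone-derived
training data. Reference (bone-derived) centres are computed
geometrically: the hip as the centre of the least-squares sphere
through femoral head surface points, the stifle as the axis point at
mid-extent of the least-squares cylinder through condyle surface
points. "Mid-extent" pins down the centroid of an otherwise infinite
primitive: the cylinder axis point at the midpoint of the data's
projected range.

## Pose estimation

**SO** solves, per segment and frame, the weighted Procrustes problem
over the visible dynamic markers (at least three required; occluded
frames are flagged, never extrapolated). The solution is closed-form
via the SVD of the weighted cross-covariance, with the standard
reflection guard (flip the smallest singular direction if the
determinant is negative).

**MKO** parameterizes the limb in 12 minimal coordinates: pelvis
translation (3) and orientation (3), femur rotation about the hip
centre (3) and tibia rotation about the stifle centre (3), all
rotations as Cardan z-x-y triplets. Forward kinematics of this chain
satisfies both spherical constraints identically, so the constrained
least-squares problem becomes an unconstrained one in 12 variables,
solved per frame by Levenberg–Marquardt (`minpack.lm`), finite-
difference Jacobian, convergence at relative cost change below 1e-10
or gradient norm below 1e-8, 200-iteration cap. Frame one starts from
the SO solution projected onto the chain; later frames warm-start from
their predecessor. The 12-DOF minimal-coordinate formulation was
preferred over 18 DOFs with explicit constraint equations because it
matches the published DOF accounting and makes constraint violation
impossible rather than merely penalized.

Cardan z-x-y is interpreted as the intrinsic (body-fixed) sequence
`Rz(flexion) Rx(adduction) Ry(rotation)` applied to the parent-to-child
relative rotation. The cited angle conventions in the field do not
always spell out intrinsic versus extrinsic composition; the intrinsic
reading is fixed here project-wide. Decomposition raises an error
within 1e-8 of gimbal lock (|adduction| = 90°) instead of silently
picking a branch; walking gait keeps all joints tens of degrees away
from that configuration, and a warning fires beyond 80°.

### Marker weighting

Weights enter both estimators as multiplicative residual weights. The
displacement-derived weighting sets each marker's weight to the
reciprocal of its *local marker displacement* — the mean distance of
its bone-frame position from its temporal mean over a gait cycle —
floored at 0.5 mm so a nearly rigid marker cannot dominate, then
normalized to mean 1 so weighted and unweighted costs are comparable.
The bone frame for each marker is re-fitted from its segment's *other*
markers (leave-one-out): with the all-marker SO frame, a quarter or
more of a marker's own deformation is absorbed into the fitted pose
and the metric underestimates the artefact; leave-one-out recovers an
injected single-marker deformation at full amplitude when the rest of
the cluster is clean (the all-marker variant remains available via
`leave_one_out = FALSE`). Either way the metric cannot see rigid
cluster motion — a structural blind spot shared by any bone estimate
derived from the same markers.

## The synthetic cohort and its artefact model

Because no marker data ship with the package, a seeded generator
provides the test surface. The reference subject is a medium (~19 kg)
dog: pelvic width 40 mm and length 100 mm at the iliac/ischial
markers, femur and tibia around 120–130 mm, treadmill walking at
0.7 m/s with a 0.6 s stride sampled at 100 Hz, three gait cycles per
trial with a 15% stride margin on both ends so every paw contact is
interior to the recording. The virtual cohort (seeds 1–8) varies
pelvic width and length within ±15%. Joint waveforms are two-harmonic
cosines rescaled so the peak-to-peak excursion is exact: 30° hip and
40° stifle flexion/extension, out-of-sagittal ranges at or below 10°.

The STA model is gait-phase-locked by construction:

* *Rigid*, per segment: a cranial translation and a flexion-axis
  rotation of the whole marker cluster about its centroid, each the sum
  of two stride-locked harmonics with seeded phases. Two harmonics
  matter: a single-phase sinusoid can end up coherently cancelling
  other stride-periodic error sources (such as a joint-centre offset),
  which is an artefact of an oversimplified spectrum rather than a
  property of skin motion. Default amplitudes follow the thigh > crus
  > pelvis ordering of canine skin mobility: 4/1.8/1.5 mm and
  2/1/0.8°.
* *Non-rigid*, per marker: a sinusoidal displacement along a seeded
  fixed direction at one or two times stride frequency, segment
  amplitudes 3/1.5/1 mm (thigh/crus/pelvis) with per-marker amplitude
  factors of 0.4–1.6, since skin motion varies strongly between
  attachment sites.
* Isotropic Gaussian measurement noise, 0.3 mm.

What this emulates: the phase-locked, sagittally dominated, thigh-heavy
character of pelvic limb STA and its split into rigid and non-rigid
parts. What it does not: true canine STA spectra (unpublished),
impact transients at paw strike, stride-to-stride variability,
marker-size and camera effects. Passing the simulation studies
therefore demonstrates correct mechanics of the estimators and the
direction of the method contrasts, not field accuracy on real dogs.

## The three simulation studies

1. **MKO vs SO** (8 subjects, default artefact, 3 cycles): per-subject
   RMSD against ground truth, per cycle then averaged, compared by the
   normality-gated paired pipeline. MKO improves hip and stifle
   flexion/extension significantly; adduction/abduction shows no
   significant improvement, and internal/external rotation can worsen —
   the known cost of a spherical stifle approximation.
2. **Joint-centre sensitivity** (20 trials): shifting the model's hip
   centre by 16.7 mm — the magnitude of landmark-regression prediction
   error reported for this marker set — along the characteristic
   caudal/proximal error direction degrades MKO flexion/extension in
   most trials.
3. **Weighting** (20 trials): with thigh markers carrying three times
   the non-rigid artefact of the other segments,
   displacement-reciprocal weighting lowers flexion/extension RMSD in
   most trials and assigns the thigh the lowest segment weights. These
   trials carry non-rigid artefact and noise only: the displacement
   metric is blind to rigid artefact by construction, so including a
   rigid component would mix an unmanipulated, randomly signed error
   source into a study whose factor is the non-rigid distribution.

Problem sizes (cohort of 8, 20 trials of one cycle each for the
sensitivity studies, 100 Hz) were chosen as the smallest giving stable
directions over the seeded replicates.

## Numerical conventions

Millimetres, degrees and Hz everywhere; right limb only (left-limb
mirroring is out of scope). Geometric fits (sphere, cylinder) minimize
orthogonal-distance cost with algebraic solutions as initializers;
solver tolerances 1e-10 relative cost, 200 iterations. The cylinder
axis is parameterized by spherical angles with the anchor constrained
to the plane through the data centroid, removing the along-axis
redundancy. Degenerate inputs (collinear markers, coplanar sphere
points, fewer than three visible markers, rank-deficient regression
designs) raise typed errors rather than returning silently wrong
results. Paw contacts are the downward zero-crossings of the foot
marker's fore-aft velocity after zero-phase 2nd-order Butterworth
low-pass filtering at 6 Hz — the cranial-most foot excursion on a
treadmill — with a 0.2 s refractory period. Gait cycles are normalized
to 101 points (0–100% inclusive, the field convention). Bland–Altman
"CI" is reported as the half-width of the 95% limits of agreement
(1.96 × SD of differences); the confidence half-width of the bias
itself is available via `ci_type = "bias"`. Bias, CI and R² pool a
subject's cycles; RMSD is computed per cycle and averaged. All
generator outputs and file writers are deterministic given their seed
and inputs (fixed column order, fixed float formatting; model YAML at
12 significant digits).

## Known limitations

Spherical joints null articular translation by construction, so stifle
translations and out-of-sagittal stifle angles from MKO should not be
over-interpreted. The displacement-based weights underestimate STA
wherever its rigid component dominates. The HJC regression default is
synthetic-trained and must be refitted for real use. Gap filling of
occluded markers is deliberately absent (a preprocessing concern), and
no hinge or deformable joint models are provided.
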