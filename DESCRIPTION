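Package: mkogait
Title: Multibody Kinematics Optimization for Canine Pelvic Limb Gait Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Marker-based estimation of three-dimensional canine pelvic limb
    kinematics during gait. Builds a subject-specific three-segment multibody
    model (pelvis, femur, tibia) from a standing marker calibration, predicts
    hip and stifle joint centres from anatomical landmarks, and tracks skin
    marker trajectories by single-body optimization (per-segment rigid fits)
    or multibody kinematics optimization (a 12 degree-of-freedom chain with
    spherical hip and stifle joints solved by Levenberg-Marquardt), with
    optional per-marker weighting for soft tissue artefact compensation.
    Includes Cardan z-x-y joint angles, gait-cycle event detection and
    normalization, Bland-Altman agreement statistics, geometric primitive
    fits (sphere, cylinder, plane) for bone-derived reference joint centres,
    a seeded synthetic gait and soft-tissue-artefact simulator, and TRC/CSV
    marker file support.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    minpack.lm,
    signal,
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
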