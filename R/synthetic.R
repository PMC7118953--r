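#' Synthetic gait and soft-tissue-artefact simulation
#'
#' Ground-truth pelvic limb motion with controllable soft tissue artefact
#' (STA) gives every estimator in the package a test surface with a known
#' answer. The generator produces a virtual subject's standing calibration,
#' a periodic gait script, STA-corrupted marker trajectories with known
#' bone poses, and bone-like point clouds for the reference joint-centre
#' fits. All outputs are pure functions of their parameters and seed.
#'
#' @name synthetic-gait
NULL

with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (has_old) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  force(expr)
}

#' Standing calibration landmarks for a virtual subject
#'
#' Generates a plausible right-pelvic-limb standing calibration for a
#' medium (~19 kg) dog in a laboratory frame with x cranial, y proximal
#' (up) and z lateral (the dog's right). Pelvic width (iliac crest
#' spacing, default 40 mm) and pelvic length (default 100 mm) scale with
#' the two shape factors so a cohort spans realistic anthropometric
#' variation.
#'
#' @param width_scale,length_scale multiplicative shape factors (1 = the
#'   reference subject).
#' @param jitter_sd landmark placement noise (mm) applied to every
#'   landmark; 0 disables.
#' @param seed RNG seed for the jitter.
#' @return named 15 x 3 landmark matrix (mm) plus attributes `true_hip`
#'   and `true_stifle`, the generating joint centres in the laboratory
#'   frame.
#' @export
synthetic_landmarks <- function(width_scale = 1, length_scale = 1,
                                jitter_sd = 0, seed = 1) {
  ws <- width_scale; ls <- length_scale
  hip <- c(-84 * ls, 363, 20 * ws)
  stifle <- hip + c(30, -115, -2)
  hock <- stifle + c(-35, -125, -4)
  L <- rbind(
    L_ILIAC_CREST  = c(0, 400, -20 * ws),
    R_ILIAC_CREST  = c(0, 400,  20 * ws),
    L_ISCHIAL_TUB  = c(-100 * ls, 398, -25 * ws),
    R_ISCHIAL_TUB  = c(-100 * ls, 398,  25 * ws),
    GT             = hip + c(2, 6, 14),
    LAT_EPICONDYLE = stifle + c(0, 2, 16),
    MED_EPICONDYLE = stifle + c(0, 2, -14),
    FIB_HEAD       = stifle + c(-8, -14, 12),
    PROX_TIB_CREST = stifle + c(14, -22, 2),
    DIST_TIB_CREST = stifle + c(8, -62, 4),
    LAT_MALLEOLUS  = hock + c(0, 3, 11),
    MED_MALLEOLUS  = hock + c(0, 3, -11),
    THIGH_TRACK_1  = hip + 0.35 * (stifle - hip) + c(28, 5, 16),
    THIGH_TRACK_2  = hip + 0.65 * (stifle - hip) + c(24, 0, 14),
    FOOT           = hock + c(40, -110, 2))
  colnames(L) <- c("x", "y", "z")
  if (jitter_sd > 0)
    L <- L + with_seed(seed, matrix(stats::rnorm(length(L), sd = jitter_sd),
                                    nrow(L), 3))
  attr(L, "true_hip") <- hip
  attr(L, "true_stifle") <- stifle
  L
}

# anthropometric ground-truth rule linking pelvic shape to the hip centre,
# used to manufacture regression training data
true_hjc_rule <- function(width, length) {
  cbind(hjc_x = -28 - 0.55 * length, hjc_z = 0.45 * width)
}

#' Synthetic training table for the hip joint centre regression
#'
#' Emulates a training database of bone-derived reference hip joint
#' centres: pelvic width and length are drawn around the reference subject
#' (+/-15%), and the reference centre follows a linear anthropometric rule
#' plus measurement noise.
#'
#' @param n number of training subjects (default 24).
#' @param noise_sd reference joint-centre noise (mm, default 2).
#' @param seed RNG seed.
#' @return data.frame with columns `width`, `length`, `hjc_x`, `hjc_z`.
#' @export
synthetic_hjc_training <- function(n = 24, noise_sd = 2, seed = 42) {
  with_seed(seed, {
    width <- 40 * stats::runif(n, 0.85, 1.15)
    length <- 100 * stats::runif(n, 0.85, 1.15)
    truth <- true_hjc_rule(width, length)
    data.frame(width = width, length = length,
               hjc_x = truth[, "hjc_x"] + stats::rnorm(n, sd = noise_sd),
               hjc_z = truth[, "hjc_z"] + stats::rnorm(n, sd = noise_sd))
  })
}

#' Default hip joint centre regression model
#'
#' The package ships a default regression fitted to its own synthetic
#' 24-subject training table (see [synthetic_hjc_training()]). For real
#' subjects, fit [fit_hjc_regression()] to bone-derived training data and
#' pass the resulting model explicitly.
#'
#' @return an `hjc_regression` model.
#' @export
default_hjc_regression <- function() {
  fit_hjc_regression(synthetic_hjc_training())
}

norm_shape <- function(h2, p1, p2) {
  phi <- seq(0, 1, length.out = 4096)
  s <- cos(2 * pi * phi + p1) + h2 * cos(4 * pi * phi + p2)
  c(smin = min(s), smax = max(s))
}

make_channel <- function(range, h2, p1, p2) {
  nm <- norm_shape(h2, p1, p2)
  list(range = range, h2 = h2, p1 = p1, p2 = p2,
       smin = nm[["smin"]], smax = nm[["smax"]])
}

eval_channel <- function(ch, phase) {
  s <- cos(2 * pi * phase + ch$p1) + ch$h2 * cos(4 * pi * phase + ch$p2)
  if (ch$smax - ch$smin < .Machine$double.eps) return(rep(0, length(phase)))
  ch$range * ((s - ch$smin) / (ch$smax - ch$smin) - 0.5)
}

#' Generate a periodic gait script
#'
#' Defines smooth periodic waveforms for the 12 chain degrees of freedom of
#' treadmill walking: pelvis translation and orientation oscillations and
#' Cardan angle excursions of the hip and stifle about the standing pose.
#' Each waveform is a two-harmonic cosine normalized so that its
#' peak-to-peak excursion equals the requested range exactly. Defaults:
#' 0.7 m/s belt speed, 0.6 s stride, 30 deg hip and 40 deg stifle
#' flexion/extension range, out-of-sagittal ranges of 10 deg or less.
#'
#' @param params optional named list overriding any of: `stride_s`,
#'   `belt_speed`, `hip_fe`, `hip_aa`, `hip_ie`, `stifle_fe`, `stifle_aa`,
#'   `stifle_ie` (deg ranges), `pelvis_trans` (mm, length 3),
#'   `pelvis_rot` (deg, length 3).
#' @param seed RNG seed for the waveform phases.
#' @return object of class `gait_script`.
#' @export
generate_gait_script <- function(params = list(), seed = 1) {
  p <- utils::modifyList(list(
    stride_s = 0.6, belt_speed = 0.7,
    hip_fe = 30, hip_aa = 8, hip_ie = 10,
    stifle_fe = 40, stifle_aa = 6, stifle_ie = 8,
    pelvis_trans = c(5, 4, 3), pelvis_rot = c(2, 1.5, 1.5)), params)
  if (!is.numeric(p$stride_s) || p$stride_s <= 0)
    stop("generate_gait_script: stride duration must be positive", call. = FALSE)
  chan_names <- c("pelvis_tx", "pelvis_ty", "pelvis_tz",
                  "pelvis_rz", "pelvis_rx", "pelvis_ry",
                  "hip_fe", "hip_aa", "hip_ie",
                  "stifle_fe", "stifle_aa", "stifle_ie")
  ranges <- c(p$pelvis_trans, p$pelvis_rot,
              p$hip_fe, p$hip_aa, p$hip_ie,
              p$stifle_fe, p$stifle_aa, p$stifle_ie)
  channels <- with_seed(seed, {
    lapply(seq_along(chan_names), function(i) {
      h2 <- stats::runif(1, 0.25, 0.45)
      make_channel(ranges[i], h2,
                   p1 = stats::runif(1, 0, 2 * pi),
                   p2 = stats::runif(1, 0, 2 * pi))
    })
  })
  names(channels) <- chan_names
  structure(list(stride_s = p$stride_s, belt_speed = p$belt_speed,
                 channels = channels, seed = seed),
            class = "gait_script")
}

#' Evaluate gait-script DOF excursions at gait phases
#'
#' @param script a `gait_script`.
#' @param phase numeric vector of gait phases (cycles; 0 = paw contact,
#'   period 1).
#' @return length(phase) x 12 matrix of DOF excursions about the standing
#'   pose (mm for pelvis translations, degrees otherwise).
#' @export
script_dof_excursions <- function(script, phase) {
  out <- vapply(script$channels, eval_channel, numeric(length(phase)),
                phase = phase)
  if (length(phase) == 1) out <- matrix(out, 1, dimnames = list(NULL, names(script$channels)))
  out
}

#' Soft tissue artefact model
#'
#' Parameterizes STA as gait-phase-locked sinusoids with two components
#' per segment: a rigid artefact (a translation along the cranial axis
#' plus a rotation about the flexion axis, applied to the whole marker
#' cluster about its centroid) that rigid per-segment fits cannot detect,
#' and a per-marker non-rigid artefact (sinusoidal displacement along a
#' random fixed direction) that deforms the array. Default amplitudes
#' follow the thigh > crus > pelvis ordering of skin motion on the canine
#' pelvic limb. Measurement noise is isotropic Gaussian.
#'
#' @param preset one of `"full"` (default), `"none"`, `"rigid"`,
#'   `"nonrigid"` — convenience presets zeroing component groups.
#' @param rigid_trans named (pelvis/femur/tibia) translation amplitudes (mm).
#' @param rigid_rot named rotation amplitudes (deg).
#' @param nonrigid named per-marker displacement amplitudes (mm).
#' @param noise_sd isotropic marker noise (mm).
#' @return object of class `sta_model`.
#' @export
sta_model <- function(preset = c("full", "none", "rigid", "nonrigid"),
                      rigid_trans = c(pelvis = 1.5, femur = 4, tibia = 1.8),
                      rigid_rot = c(pelvis = 0.8, femur = 2, tibia = 1),
                      nonrigid = c(pelvis = 1, femur = 3, tibia = 1.5),
                      noise_sd = 0.3) {
  preset <- match.arg(preset)
  z3 <- c(pelvis = 0, femur = 0, tibia = 0)
  if (preset == "none") { rigid_trans <- rigid_rot <- nonrigid <- z3; noise_sd <- 0 }
  if (preset == "rigid") nonrigid <- z3
  if (preset == "nonrigid") { rigid_trans <- z3; rigid_rot <- z3 }
  stopifnot(all(rigid_trans >= 0), all(rigid_rot >= 0),
            all(nonrigid >= 0), noise_sd >= 0)
  structure(list(rigid_trans = rigid_trans, rigid_rot = rigid_rot,
                 nonrigid = nonrigid, noise_sd = noise_sd, preset = preset),
            class = "sta_model")
}

calibration_dof <- function(model) {
  fr <- model$frames
  c(fr$pelvis$t, rotation_to_cardan_zxy(fr$pelvis$R),
    rotation_to_cardan_zxy(t(fr$pelvis$R) %*% fr$femur$R),
    rotation_to_cardan_zxy(t(fr$femur$R) %*% fr$tibia$R))
}

#' Synthesize a marker trial with known ground truth
#'
#' Drives the 12-DOF chain of `model` with the gait script, computes
#' ground-truth segment poses and joint angles by forward kinematics, and
#' renders skin markers as the template positions corrupted by the STA
#' model. The foot marker is synthesized so that its cranial-most
#' excursion (fore-aft velocity downward zero-crossing) falls exactly on
#' the true paw contacts at integer stride boundaries.
#'
#' @param model a `multibody_model` (the generating ground truth).
#' @param script a `gait_script`.
#' @param sta an `sta_model`; default full artefact.
#' @param n_cycles number of gait cycles (default 3).
#' @param rate_hz marker sampling rate (default 100 Hz).
#' @param pad_cycles extra recording margin before the first and after the
#'   last contact, as a fraction of a stride (default 0.15), so every true
#'   contact is interior to the series and detectable.
#' @param seed RNG seed (artefact directions/phases and noise).
#' @return object of class `synthetic_trial`: `trajectories`
#'   (a `marker_trajectories`), `truth_poses` (per-frame pose list),
#'   `truth_angles` (frames x 6 matrix, deg), `truth_dof` (frames x 12),
#'   `contacts` (frame indices), `model`, `script`, `sta`.
#' @export
synthesize_trial <- function(model, script, sta = sta_model(),
                             n_cycles = 3, rate_hz = 100, pad_cycles = 0.15,
                             seed = 1) {
  if (n_cycles < 1 || rate_hz <= 0)
    stop("synthesize_trial: need n_cycles >= 1 and positive rate", call. = FALSE)
  stride <- script$stride_s
  pad <- round(pad_cycles * stride * rate_hz) / rate_hz
  t <- seq(-pad, n_cycles * stride + pad, by = 1 / rate_hz)
  n <- length(t)
  phase <- t / stride
  q0 <- calibration_dof(model)
  dq <- script_dof_excursions(script, phase)
  Q <- sweep(dq, 2, q0, "+")

  seg_names <- c("pelvis", "femur", "tibia")
  dyn_by_seg <- lapply(model$templates[seg_names], function(tm)
    intersect(rownames(tm), model$dynamic))
  marker_names <- c(unlist(dyn_by_seg, use.names = FALSE), "FOOT")
  m <- length(marker_names)

  # seeded artefact structure: per-segment phases, per-marker directions
  art <- with_seed(seed, {
    seg_phase <- lapply(seg_names, function(s)
      list(tr = stats::runif(2, 0, 2 * pi), rot = stats::runif(2, 0, 2 * pi)))
    names(seg_phase) <- seg_names
    mk <- lapply(setdiff(marker_names, "FOOT"), function(mn) {
      v <- stats::rnorm(3); v <- v / sqrt(sum(v^2))
      # skin motion varies strongly between attachment sites
      list(dir = v, freq = sample(1:2, 1),
           phase = stats::runif(1, 0, 2 * pi),
           amp_scale = stats::runif(1, 0.4, 1.6))
    })
    names(mk) <- setdiff(marker_names, "FOOT")
    list(seg = seg_phase, mk = mk)
  })

  xyz <- array(NA_real_, dim = c(n, 3, m),
               dimnames = list(NULL, c("x", "y", "z"), marker_names))
  truth_poses <- vector("list", n)
  truth_angles <- matrix(NA_real_, n, 6,
                         dimnames = list(NULL, c("hip_fe", "hip_aa", "hip_ie",
                                                 "stifle_fe", "stifle_aa", "stifle_ie")))
  for (k in seq_len(n)) {
    qk <- Q[k, ]
    poses <- fk_poses(model, qk)
    truth_poses[[k]] <- poses
    truth_angles[k, ] <- c(qk[7:9], qk[10:12])
    ph <- phase[k] %% 1
    for (s in seg_names) {
      dyn <- dyn_by_seg[[s]]
      lab <- rt_apply(poses[[s]], model$templates[[s]][dyn, , drop = FALSE])
      # rigid cluster artefact: cranial translation + flexion-axis rotation,
      # two stride-locked harmonics (skin motion is not a pure sinusoid)
      h2 <- function(amp, phases)
        amp * (0.8 * sin(2 * pi * ph + phases[1]) +
               0.45 * sin(4 * pi * ph + phases[2]))
      at <- h2(sta$rigid_trans[[s]], art$seg[[s]]$tr)
      ar <- h2(sta$rigid_rot[[s]], art$seg[[s]]$rot)
      ctr <- colMeans(lab)
      Ra <- elem_rot("z", ar * DEG2RAD)
      lab <- sweep(sweep(lab, 2, ctr) %*% t(Ra), 2, ctr + c(at, 0, 0), "+")
      for (mn in dyn) {
        a <- art$mk[[mn]]
        lab[mn, ] <- lab[mn, ] + sta$nonrigid[[s]] * a$amp_scale *
          sin(2 * pi * a$freq * ph + a$phase) * a$dir
      }
      xyz[k, , dyn] <- t(lab)
    }
  }
  # foot marker: fore-aft cosine peaking at contact, vertical swing bump
  foot_base <- c(-49, 13, 16)
  xyz[, 1, "FOOT"] <- foot_base[1] + 100 * (cos(2 * pi * phase) - 1) / 2
  xyz[, 2, "FOOT"] <- foot_base[2] + 35 * (0.5 - 0.5 * cos(2 * pi * phase))^3
  xyz[, 3, "FOOT"] <- foot_base[3]
  if (sta$noise_sd > 0)
    xyz <- xyz + with_seed(seed + 1L,
      array(stats::rnorm(length(xyz), sd = sta$noise_sd), dim = dim(xyz)))

  contacts <- which(abs(phase - round(phase)) < 0.5 / (rate_hz * stride) &
                    round(phase) >= 0 & round(phase) <= n_cycles)
  traj <- marker_trajectories(xyz, rate_hz, time = t - t[1])
  structure(list(trajectories = traj, truth_poses = truth_poses,
                 truth_angles = truth_angles, truth_dof = Q,
                 contacts = contacts, model = model, script = script,
                 sta = sta),
            class = "synthetic_trial")
}

#' Synthesize bone-like point clouds for joint-centre reference fits
#'
#' Samples a spherical cap about the true hip centre (femoral head) and
#' two partial cylindrical bands about the true stifle flexion axis
#' (bilateral condyles), with optional isotropic noise.
#'
#' @param true_hjc length-3 hip centre (mm, laboratory frame).
#' @param true_sjc_axis list with `point` (length-3, the mid-axis stifle
#'   centre) and `direction` (length-3 axis direction).
#' @param params optional overrides: `head_radius` (11), `condyle_radius`
#'   (14), `n_head` (400), `n_condyle` (600), `cap_deg` (75), `arc_deg`
#'   (140), `band_mm` (c(4, 12)), `noise_sd` (0).
#' @param seed RNG seed.
#' @return list with `femoral_head` and `condyles` point matrices (mm).
#' @export
synthesize_bone_clouds <- function(true_hjc, true_sjc_axis,
                                   params = list(), seed = 1) {
  p <- utils::modifyList(list(head_radius = 11, condyle_radius = 14,
                              n_head = 400, n_condyle = 600, cap_deg = 75,
                              arc_deg = 140, band_mm = c(4, 12),
                              noise_sd = 0), params)
  if (p$head_radius <= 0 || p$condyle_radius <= 0 || p$cap_deg <= 0 ||
      p$arc_deg <= 0 || p$band_mm[2] <= p$band_mm[1])
    stop("synthesize_bone_clouds: empty sampling region", call. = FALSE)
  a <- unit(as.numeric(true_sjc_axis$direction))
  ref <- if (abs(a[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
  u <- orthounit(ref, a)
  v <- cross3(a, u)
  with_seed(seed, {
    # spherical cap about +y of the lab (dorsal), polar angle <= cap_deg
    ct <- stats::runif(p$n_head, cos(p$cap_deg * DEG2RAD), 1)
    st <- sqrt(1 - ct^2)
    az <- stats::runif(p$n_head, 0, 2 * pi)
    dirs <- cbind(st * cos(az), ct, st * sin(az))
    head <- sweep(p$head_radius * dirs, 2, as.numeric(true_hjc), "+")
    # two condyle bands, one per side of the mid-axis point
    half <- p$n_condyle %/% 2
    sgn <- rep(c(-1, 1), c(half, p$n_condyle - half))
    s <- sgn * stats::runif(p$n_condyle, p$band_mm[1], p$band_mm[2])
    th <- stats::runif(p$n_condyle, -p$arc_deg / 2, p$arc_deg / 2) * DEG2RAD
    cond <- sweep(outer(s, a) + p$condyle_radius *
                    (outer(cos(th), u) + outer(sin(th), v)),
                  2, as.numeric(true_sjc_axis$point), "+")
    if (p$noise_sd > 0) {
      head <- head + matrix(stats::rnorm(length(head), sd = p$noise_sd),
                            nrow(head), 3)
      cond <- cond + matrix(stats::rnorm(length(cond), sd = p$noise_sd),
                            nrow(cond), 3)
    }
    colnames(head) <- colnames(cond) <- c("x", "y", "z")
    list(femoral_head = head, condyles = cond)
  })
}

#' Build a virtual subject: calibration model plus anthropometry
#'
#' One virtual cohort member: seeded shape factors within +/-15% of the
#' reference subject, the standing calibration, and the assembled
#' multibody model (predicted joint centres via the supplied regression).
#'
#' @param seed subject seed (cohort convention: seeds 1..8).
#' @param hjc_model regression for joint-centre prediction; default
#'   [default_hjc_regression()].
#' @param jitter_sd calibration landmark noise (mm, default 0).
#' @return list with `landmarks`, `model`, `width_scale`, `length_scale`.
#' @export
synthetic_subject <- function(seed, hjc_model = default_hjc_regression(),
                              jitter_sd = 0) {
  sc <- with_seed(seed * 1000L + 7L, stats::runif(2, 0.85, 1.15))
  lm <- synthetic_landmarks(width_scale = sc[1], length_scale = sc[2],
                            jitter_sd = jitter_sd, seed = seed)
  list(landmarks = lm, model = calibrate_model(lm, hjc_model),
       width_scale = sc[1], length_scale = sc[2])
}
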