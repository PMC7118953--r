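#' Simulation studies on the virtual cohort
#'
#' Desk-scale re-creations of the three evaluation comparisons: multibody
#' versus single-body optimization, sensitivity to hip joint centre
#' error, and displacement-reciprocal marker weighting. Each experiment
#' generates seeded synthetic trials with known ground truth, runs the
#' package's own tracking pipeline, and summarizes joint-angle errors per
#' trial. All functions are deterministic given their seeds.
#'
#' @name simulation-studies
NULL

angle_components <- function() {
  c("hip_fe", "hip_aa", "hip_ie", "stifle_fe", "stifle_aa", "stifle_ie")
}

#' Per-subject RMSD between tracked and ground-truth angles
#'
#' Runs the full analysis pipeline on one synthetic trial: joint angles
#' from the tracking result, paw contacts from the foot marker,
#' normalization of both tracked and true angles to 101-point gait
#' cycles, and RMSD per component averaged over the trial's cycles.
#'
#' @param tracking a `tracking_result`.
#' @param trial the generating `synthetic_trial`.
#' @return named numeric (deg): RMSD per angle component.
#' @export
trial_rmsd <- function(tracking, trial) {
  ang <- compute_joint_angles(tracking)
  contacts <- detect_paw_contacts(trial$trajectories$xyz[, , "FOOT"],
                                  trial$trajectories$rate_hz)
  test <- normalize_to_gait_cycle(ang, contacts)
  ref <- normalize_to_gait_cycle(trial$truth_angles, contacts)
  stats::setNames(cycle_rmsd(test, ref), angle_components())
}

#' Shift a model's hip joint centre by a fixed error
#'
#' Displaces the hip joint centre by `magnitude` mm along `direction`
#' (pelvic-frame components; default along the observed pattern of
#' landmark-regression prediction error: caudal and proximal with a small
#' lateral component), keeping the model self-consistent by re-expressing
#' the shifted centre in the femoral frame through the calibration poses.
#'
#' @param model a `multibody_model`.
#' @param magnitude shift magnitude (mm; default 16.7).
#' @param direction length-3 direction in the pelvic frame (normalized
#'   internally).
#' @return the perturbed `multibody_model`.
#' @export
perturb_hjc <- function(model, magnitude = 16.7,
                        direction = c(-6.2, 11.6, 1.8)) {
  dir <- unit(as.numeric(direction))
  cn <- model$centres
  cn$hjc_in_pelvis <- cn$hjc_in_pelvis + magnitude * dir
  hjc_lab <- rt_apply(model$frames$pelvis, cn$hjc_in_pelvis)
  cn$hjc_in_femur <- rt_apply(rt_inverse(model$frames$femur), hjc_lab)
  model$centres <- cn
  model
}

#' Multibody versus single-body optimization on the virtual cohort
#'
#' For each virtual subject: synthesize a default-artefact trial, track
#' it with SO and MKO, and compute per-subject RMSD against ground truth
#' over the trial's gait cycles. Paired comparisons (normality-gated)
#' test MKO against SO per angle component.
#'
#' @param n_subjects cohort size (default 8, seeds `seed_base + 1..n`).
#' @param sta an `sta_model` (default full artefact).
#' @param n_cycles gait cycles per trial (default 3).
#' @param rate_hz sampling rate (default 100).
#' @param seed_base offset added to subject seeds (default 0).
#' @param weights optional per-marker weights used for the MKO pass.
#' @return list: `so_rmsd`, `mko_rmsd` (subjects x components matrices)
#'   and `tests` (per-component `paired_comparison` of MKO vs SO).
#' @export
experiment_mko_vs_so <- function(n_subjects = 8, sta = sta_model(),
                                 n_cycles = 3, rate_hz = 100,
                                 seed_base = 0, weights = NULL) {
  comp <- angle_components()
  so_r <- mko_r <- matrix(NA_real_, n_subjects, 6,
                          dimnames = list(NULL, comp))
  for (i in seq_len(n_subjects)) {
    s <- seed_base + i
    subj <- synthetic_subject(s)
    trial <- synthesize_trial(subj$model, generate_gait_script(seed = s),
                              sta, n_cycles = n_cycles, rate_hz = rate_hz,
                              seed = s)
    so_r[i, ] <- trial_rmsd(so_track(trial$trajectories, subj$model), trial)
    mko_r[i, ] <- trial_rmsd(mko_track(trial$trajectories, subj$model,
                                       weights), trial)
  }
  tests <- lapply(comp, function(j) paired_compare(mko_r[, j], so_r[, j]))
  names(tests) <- comp
  list(so_rmsd = so_r, mko_rmsd = mko_r, tests = tests)
}

#' Sensitivity of MKO to hip joint centre error
#'
#' Tracks each seeded trial twice with MKO: once with the generating
#' (true-centre) model and once with the hip joint centre shifted by
#' `magnitude` mm ([perturb_hjc()]). Reports the flexion/extension RMSD
#' (mean of hip and stifle) for both models per trial.
#'
#' @param n_trials number of seeded trials (default 20, seeds
#'   `seed_base + 1..n`; trial artefact seeds offset by 100).
#' @param magnitude joint-centre shift (mm, default 16.7).
#' @param sta an `sta_model` (default full artefact).
#' @param n_cycles,rate_hz trial dimensions (defaults 1 cycle, 100 Hz).
#' @param seed_base seed offset (default 0).
#' @return list: `rmsd_true`, `rmsd_perturbed` (per-trial
#'   flexion/extension RMSD, deg), `n_worse` (trials where the perturbed
#'   model is worse).
#' @export
experiment_hjc_perturbation <- function(n_trials = 20, magnitude = 16.7,
                                        sta = sta_model(), n_cycles = 1,
                                        rate_hz = 100, seed_base = 0) {
  fe <- c("hip_fe", "stifle_fe")
  r_true <- r_pert <- numeric(n_trials)
  for (i in seq_len(n_trials)) {
    s <- seed_base + i
    subj <- synthetic_subject(s)
    trial <- synthesize_trial(subj$model, generate_gait_script(seed = s),
                              sta, n_cycles = n_cycles, rate_hz = rate_hz,
                              seed = s + 100)
    r_true[i] <- mean(trial_rmsd(
      mko_track(trial$trajectories, subj$model), trial)[fe])
    r_pert[i] <- mean(trial_rmsd(
      mko_track(trial$trajectories, perturb_hjc(subj$model, magnitude)),
      trial)[fe])
  }
  list(rmsd_true = r_true, rmsd_perturbed = r_pert,
       n_worse = sum(r_pert > r_true))
}

#' Effect of displacement-reciprocal marker weighting
#'
#' Thigh markers receive `thigh_factor` times the non-rigid artefact of
#' the other segments; each seeded trial is tracked with MKO twice, with
#' uniform weights and with weights set to the reciprocal of the local
#' marker displacement estimated from the trial's own single-body
#' solution. The trials carry non-rigid artefact and measurement noise
#' only: displacement-derived weights cannot see the rigid artefact
#' component (it moves local marker positions not at all), so zeroing it
#' isolates the factor this experiment manipulates. Reports
#' flexion/extension RMSD per trial and the mean computed weight per
#' segment.
#'
#' @inheritParams experiment_hjc_perturbation
#' @param thigh_factor non-rigid artefact inflation for thigh markers
#'   (default 3).
#' @param base_nonrigid non-rigid amplitude of the non-thigh segments
#'   (mm, default 1.5).
#' @return list: `rmsd_uniform`, `rmsd_weighted` (per-trial, deg),
#'   `n_better` (trials where weighting lowers the RMSD),
#'   `segment_weights` (trials x 3 matrix of mean weight per segment).
#' @export
experiment_marker_weighting <- function(n_trials = 20, thigh_factor = 3,
                                        base_nonrigid = 1.5,
                                        n_cycles = 1, rate_hz = 100,
                                        seed_base = 0) {
  fe <- c("hip_fe", "stifle_fe")
  sta <- sta_model(preset = "nonrigid",
                   nonrigid = c(pelvis = base_nonrigid,
                                femur = thigh_factor * base_nonrigid,
                                tibia = base_nonrigid))
  seg <- segment_markers()
  r_unw <- r_w <- numeric(n_trials)
  seg_w <- matrix(NA_real_, n_trials, 3,
                  dimnames = list(NULL, names(seg)))
  for (i in seq_len(n_trials)) {
    s <- seed_base + i
    subj <- synthetic_subject(s)
    trial <- synthesize_trial(subj$model, generate_gait_script(seed = s),
                              sta, n_cycles = n_cycles, rate_hz = rate_hz,
                              seed = s + 200)
    so <- so_track(trial$trajectories, subj$model)
    disp <- local_marker_displacement(trial$trajectories, so, subj$model)
    w <- weights_from_displacement(disp)
    seg_w[i, ] <- vapply(seg, function(mk)
      mean(w[intersect(mk, names(w))]), numeric(1))
    r_unw[i] <- mean(trial_rmsd(
      mko_track(trial$trajectories, subj$model), trial)[fe])
    r_w[i] <- mean(trial_rmsd(
      mko_track(trial$trajectories, subj$model, w), trial)[fe])
  }
  list(rmsd_uniform = r_unw, rmsd_weighted = r_w,
       n_better = sum(r_w < r_unw), segment_weights = seg_w)
}
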