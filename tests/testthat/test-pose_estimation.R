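zero_sta_trial <- function(seed = 2, n_cycles = 1, rate_hz = 50) {
  sub <- ref_subject()
  synthesize_trial(sub$model, generate_gait_script(seed = seed),
                   sta_model("none"), n_cycles = n_cycles,
                   rate_hz = rate_hz, seed = seed)
}

test_that("single-body optimization recovers artefact-free poses exactly", {
  sub <- ref_subject()
  trial <- zero_sta_trial()
  so <- so_track(trial$trajectories, sub$model)
  expect_true(all(so$valid))
  for (k in c(1, 10, trial$trajectories$n_frames)) {
    for (s in c("pelvis", "femur", "tibia")) {
      expect_lt(norm(so$poses[[k]][[s]]$R - trial$truth_poses[[k]][[s]]$R, "F"),
                1e-9)
      expect_lt(max(abs(so$poses[[k]][[s]]$t - trial$truth_poses[[k]][[s]]$t)),
                1e-9)
    }
  }
  expect_lt(max(so$residual), 1e-9)
})

test_that("a rigid whole-cluster artefact passes straight into the SO pose", {
  sub <- ref_subject()
  trial <- zero_sta_trial()
  traj <- trial$trajectories
  femur_dyn <- intersect(rownames(sub$model$templates$femur),
                         sub$model$dynamic)
  # constant 8 mm cranial offset on every femur marker
  traj$xyz[, 1, femur_dyn] <- traj$xyz[, 1, femur_dyn] + 8
  so <- so_track(traj, sub$model)
  for (k in c(1, 15)) {
    expect_equal(so$poses[[k]]$femur$t - trial$truth_poses[[k]]$femur$t,
                 c(8, 0, 0), tolerance = 1e-9)
    expect_lt(norm(so$poses[[k]]$femur$R - trial$truth_poses[[k]]$femur$R, "F"),
              1e-9)
    # the other segments are untouched
    expect_lt(max(abs(so$poses[[k]]$pelvis$t - trial$truth_poses[[k]]$pelvis$t)),
              1e-9)
  }
})

test_that("an occluded marker drops to the remaining-marker fit", {
  sub <- ref_subject()
  trial <- zero_sta_trial()
  traj <- trial$trajectories
  k <- 7
  traj$xyz[k, , "THIGH_TRACK_1"] <- NA
  traj <- marker_trajectories(traj$xyz, traj$rate_hz, traj$time)
  so <- so_track(traj, sub$model)
  expect_true(so$valid[k, "femur"])
  femur_dyn <- setdiff(intersect(rownames(sub$model$templates$femur),
                                 sub$model$dynamic), "THIGH_TRACK_1")
  direct <- weighted_rigid_fit(sub$model$templates$femur[femur_dyn, ],
                               t(trial$trajectories$xyz[k, , femur_dyn]))
  expect_equal(so$poses[[k]]$femur$R, direct$R, tolerance = 1e-12)
  expect_equal(so$poses[[k]]$femur$t, direct$t, tolerance = 1e-12)
})

test_that("the chain solver recovers known DOFs and is weight-scale invariant", {
  sub <- ref_subject()
  model <- sub$model
  fr <- model$frames
  q_true <- poses_to_dof(list(pelvis = fr$pelvis, femur = fr$femur,
                              tibia = fr$tibia)) +
    c(3, -2, 5, 2, -1, 1.5, 8, -2, 3, -12, 1, -2)
  obs <- fk_markers(model, q_true)
  init <- q_true + c(rep(5, 3), rep(5, 9))
  sol <- mko_solve_frame(obs, model, init = init)
  expect_true(sol$converged)
  expect_equal(sol$q, q_true, tolerance = 1e-6)
  expect_lt(sol$residual, 1e-7)
  # uniformly scaled weights leave the optimum unchanged
  w10 <- stats::setNames(rep(10, length(model$weights)),
                         names(model$weights))
  sol10 <- mko_solve_frame(obs, model, weights = w10, init = init)
  expect_equal(sol10$q, sol$q, tolerance = 1e-8)
  # zero weight on a marker equals removing it
  obs_n <- obs + matrix(rnorm(length(obs), sd = 1), nrow(obs), 3)
  w0 <- model$weights
  w0["THIGH_TRACK_1"] <- 0
  sol_w0 <- mko_solve_frame(obs_n, model, weights = w0, init = init)
  sol_del <- mko_solve_frame(obs_n[rownames(obs_n) != "THIGH_TRACK_1", ],
                             model, init = init)
  expect_equal(sol_w0$q, sol_del$q, tolerance = 1e-6)
})

test_that("multibody tracking enforces the spherical constraints exactly", {
  sub <- ref_subject()
  trial <- zero_sta_trial(seed = 5)
  mko <- mko_track(trial$trajectories, sub$model)
  expect_true(all(mko$converged))
  cn <- sub$model$centres
  for (k in seq_along(mko$poses)) {
    gap_h <- rt_apply(mko$poses[[k]]$pelvis, cn$hjc_in_pelvis) -
      rt_apply(mko$poses[[k]]$femur, cn$hjc_in_femur)
    gap_s <- rt_apply(mko$poses[[k]]$femur, cn$sjc_in_femur) -
      rt_apply(mko$poses[[k]]$tibia, cn$sjc_in_tibia)
    expect_lt(max(abs(c(gap_h, gap_s))), 1e-9)
  }
  ang <- compute_joint_angles(mko)
  expect_lt(max(abs(ang - trial$truth_angles)), 0.01)
})

test_that("a single-frame trajectory reduces to one chain solve with SO init", {
  sub <- ref_subject()
  trial <- zero_sta_trial(seed = 6)
  traj1 <- marker_trajectories(
    trial$trajectories$xyz[1, , , drop = FALSE], trial$trajectories$rate_hz)
  res <- mko_track(traj1, sub$model)
  so1 <- so_track(traj1, sub$model)
  direct <- mko_solve_frame(t(traj1$xyz[1, , ]), sub$model,
                            init = poses_to_dof(so1$poses[[1]]))
  expect_equal(res$dof[1, ], direct$q, tolerance = 1e-9)
})

test_that("the optimizer never worsens its single-body initialization", {
  sub <- ref_subject()
  trial <- synthesize_trial(sub$model, generate_gait_script(seed = 9),
                            sta_model("full"), n_cycles = 1, rate_hz = 50,
                            seed = 9)
  traj <- trial$trajectories
  so <- so_track(traj, sub$model)
  model <- sub$model
  cost_at <- function(q, k) {
    obs <- t(traj$xyz[k, , ])
    pred <- fk_markers(model, q)
    sum(model$weights[rownames(pred)] *
          rowSums((pred - obs[rownames(pred), ])^2))
  }
  mko <- mko_track(traj, model)
  k <- 1
  expect_lte(cost_at(mko$dof[k, ], k),
             cost_at(poses_to_dof(so$poses[[k]]), k) + 1e-9)
})

test_that("local marker displacement recovers injected deformation", {
  sub <- ref_subject()
  trial <- zero_sta_trial(seed = 2, rate_hz = 100)
  traj <- trial$trajectories
  so0 <- so_track(traj, sub$model)
  d0 <- local_marker_displacement(traj, so0, sub$model)
  expect_lt(max(d0), 1e-9)
  # sinusoidal artefact on one marker, closed-form expected amplitude
  n <- traj$n_frames
  inj <- 3 * sin(2 * pi * (seq_len(n) - 1) / (n - 1) + 0.4)
  traj$xyz[, 1, "THIGH_TRACK_1"] <- traj$xyz[, 1, "THIGH_TRACK_1"] + inj
  so <- so_track(traj, sub$model)
  d <- local_marker_displacement(traj, so, sub$model)
  expected <- mean(abs(inj - mean(inj)))
  expect_lt(abs(d[["THIGH_TRACK_1"]] - expected) / expected, 0.02)
  # a purely rigid cluster artefact is invisible to the metric
  sta_r <- sta_model("rigid")
  sta_r$noise_sd <- 0
  trial_r <- synthesize_trial(sub$model, generate_gait_script(seed = 2),
                              sta_r, n_cycles = 1, rate_hz = 100, seed = 2)
  so_r <- so_track(trial_r$trajectories, sub$model)
  d_r <- local_marker_displacement(trial_r$trajectories, so_r, sub$model)
  expect_lt(max(d_r), 1e-9)
})

test_that("displacement-reciprocal weights follow the stated normalization", {
  w <- weights_from_displacement(c(A = 2, B = 4), floor = 0.5)
  expect_equal(unname(w), c(4 / 3, 2 / 3), tolerance = 1e-12)
  expect_equal(unname(weights_from_displacement(c(A = 3, B = 3, C = 3))),
               rep(1, 3))
  # floor caps the reciprocal of a near-zero displacement
  w2 <- weights_from_displacement(c(A = 0, B = 0.1), floor = 0.1)
  expect_equal(unname(w2), c(1, 1), tolerance = 1e-12)
  expect_error(weights_from_displacement(numeric(0)), "empty")
})
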