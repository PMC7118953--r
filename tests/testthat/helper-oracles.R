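# Shared fixtures and independent oracles for the test suite.

# random proper rotation from Cardan angles away from gimbal lock
rand_rotation <- function(beta_max = 85) {
  cardan_zxy_to_rotation(c(stats::runif(1, -180, 180),
                           stats::runif(1, -beta_max, beta_max),
                           stats::runif(1, -180, 180)))
}

rotation_angle_rad <- function(R1, R2) {
  tr <- sum(diag(crossprod(R1, R2)))
  acos(max(-1, min(1, (tr - 1) / 2)))
}

# brute-force oracle for the weighted rigid registration: multi-start
# quasi-Newton minimization of the weighted cost over Cardan angles and
# translation, independent of the closed-form SVD path
oracle_rigid_fit <- function(template, observed, weights, n_starts = 20) {
  w <- if (is.null(weights)) rep(1, nrow(template)) else weights
  cost <- function(par) {
    R <- cardan_zxy_to_rotation(par[1:3] * 180 / pi)
    r <- sweep(template %*% t(R), 2, par[4:6], "+") - observed
    sum(w * rowSums(r^2))
  }
  t_guess <- colMeans(observed) - colMeans(template)
  best <- NULL
  for (i in seq_len(n_starts)) {
    start <- c(stats::runif(3, -pi / 2, pi / 2),
               t_guess + stats::rnorm(3, sd = 5))
    fit <- stats::optim(start, cost, method = "BFGS",
                        control = list(reltol = 1e-15, maxit = 1000))
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  list(R = cardan_zxy_to_rotation(best$par[1:3] * 180 / pi),
       t = best$par[4:6], cost = best$value)
}

# one cached reference subject for tests that only need a valid model
ref_subject <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      lm <- synthetic_landmarks()
      cache <<- list(landmarks = lm, model = calibrate_model(lm))
    }
    cache
  }
})

# full landmark set with an exactly planar pelvis (y = 0 plane) so the
# posterior pelvic plane and HJC y-rule can be checked in closed form
planar_pelvis_landmarks <- function(gt_y = 25) {
  rbind(
    L_ILIAC_CREST  = c(0, 0, -20),
    R_ILIAC_CREST  = c(0, 0, 20),
    L_ISCHIAL_TUB  = c(-100, 0, -25),
    R_ISCHIAL_TUB  = c(-100, 0, 25),
    GT             = c(-80, gt_y, 30),
    LAT_EPICONDYLE = c(-60, -110, 40),
    MED_EPICONDYLE = c(-60, -110, 10),
    FIB_HEAD       = c(-65, -125, 35),
    PROX_TIB_CREST = c(-45, -132, 28),
    DIST_TIB_CREST = c(-50, -170, 30),
    LAT_MALLEOLUS  = c(-85, -230, 38),
    MED_MALLEOLUS  = c(-85, -230, 16),
    THIGH_TRACK_1  = c(-45, -40, 45),
    THIGH_TRACK_2  = c(-52, -75, 42),
    FOOT           = c(-40, -280, 25))
}

zero_hjc_regression <- function() {
  tr <- data.frame(width = c(30, 40, 50, 45), length = c(90, 100, 110, 95),
                   hjc_x = 0, hjc_z = 0)
  m <- fit_hjc_regression(tr)
  m$x_coef[] <- 0
  m$z_coef[] <- 0
  m
}

# observed markers for one frame from known chain DOFs
fk_markers <- function(model, q) {
  poses <- fk_poses(model, q)
  do.call(rbind, lapply(c("pelvis", "femur", "tibia"), function(s) {
    tm <- model$templates[[s]]
    dyn <- intersect(rownames(tm), model$dynamic)
    rt_apply(poses[[s]], tm[dyn, , drop = FALSE])
  }))
}
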