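test_that("anatomical frames follow the axis conventions", {
  # pelvic landmarks laid out on the canonical axes give an identity frame
  L <- planar_pelvis_landmarks()
  fr <- build_anatomical_frames(L)
  expect_equal(fr$pelvis$R, diag(3), tolerance = 1e-12)
  expect_equal(fr$pelvis$t, c(0, 0, 0), tolerance = 1e-12)
  # every frame is a proper right-handed rotation
  fr2 <- build_anatomical_frames(ref_subject()$landmarks)
  for (s in names(fr2)) {
    expect_equal(det(fr2[[s]]$R), 1, tolerance = 1e-9)
    expect_lt(norm(crossprod(fr2[[s]]$R) - diag(3), "F"), 1e-9)
  }
  # femoral y points from the epicondyle midpoint to GT
  mid_epi <- (L["LAT_EPICONDYLE", ] + L["MED_EPICONDYLE", ]) / 2
  fy <- (L["GT", ] - mid_epi) / sqrt(sum((L["GT", ] - mid_epi)^2))
  expect_equal(as.numeric(fr$femur$R[, 2]), as.numeric(fy), tolerance = 1e-12)
  Lm <- ref_subject()$landmarks
  expect_error(build_anatomical_frames(Lm[rownames(Lm) != "GT", ]), "GT")
})

test_that("frames are equivariant and templates invariant under lab-frame motion", {
  set.seed(101)
  L <- ref_subject()$landmarks
  fr <- build_anatomical_frames(L)
  tmpl <- build_marker_templates(L, fr)
  g <- rigid_transform(rand_rotation(), c(500, -200, 120))
  L2 <- rt_apply(g, L)
  rownames(L2) <- rownames(L)
  fr2 <- build_anatomical_frames(L2)
  tmpl2 <- build_marker_templates(L2, fr2)
  for (s in names(fr)) {
    comp <- rt_compose(g, fr[[s]])
    expect_equal(fr2[[s]]$R, comp$R, tolerance = 1e-9)
    expect_equal(fr2[[s]]$t, comp$t, tolerance = 1e-9)
    expect_equal(tmpl2[[s]], tmpl[[s]], tolerance = 1e-9)
  }
})

test_that("marker templates express landmarks in their segment frames", {
  L <- ref_subject()$landmarks
  fr <- build_anatomical_frames(L)
  tmpl <- build_marker_templates(L, fr)
  # round trip: frame pose applied to template reproduces the lab points
  for (s in names(tmpl)) {
    lab <- rt_apply(fr[[s]], tmpl[[s]])
    expect_equal(lab, L[rownames(tmpl[[s]]), ], tolerance = 1e-10,
                 ignore_attr = TRUE)
  }
  # a landmark at the femoral origin has a zero template coordinate
  L3 <- L
  L3["THIGH_TRACK_1", ] <- fr$femur$t
  tmpl3 <- build_marker_templates(L3, build_anatomical_frames(L3))
  expect_equal(as.numeric(tmpl3$femur["THIGH_TRACK_1", ]), c(0, 0, 0),
               tolerance = 1e-10)
})

test_that("HJC regression solves the two coordinate equations by least squares", {
  # noiseless recovery of a stated linear model
  set.seed(111)
  w <- runif(10, 30, 50); l <- runif(10, 85, 115)
  tr <- data.frame(width = w, length = l,
                   hjc_x = -30 - 0.5 * w - 0.3 * l,
                   hjc_z = -5 + 0.1 * w)
  m <- fit_hjc_regression(tr)
  expect_equal(unname(m$x_coef), c(-30, -0.5, -0.3), tolerance = 1e-9)
  expect_equal(unname(m$z_coef), c(-5, 0.1, 0), tolerance = 1e-9)
  expect_lt(max(m$rms), 1e-9)
  expect_error(fit_hjc_regression(tr[1:2, ]), "rank-deficient")
  # noisy fit equals an independent normal-equations solve
  trn <- synthetic_hjc_training(n = 24, noise_sd = 2, seed = 5)
  mn <- fit_hjc_regression(trn)
  X <- cbind(1, trn$width, trn$length)
  beta_x <- solve(t(X) %*% X, t(X) %*% trn$hjc_x)
  beta_z <- solve(t(X) %*% X, t(X) %*% trn$hjc_z)
  expect_equal(unname(mn$x_coef), as.numeric(beta_x), tolerance = 1e-8)
  expect_equal(unname(mn$z_coef), as.numeric(beta_z), tolerance = 1e-8)
})

test_that("regression coefficient error shrinks as the training cohort grows", {
  rmse <- sapply(c(24, 240), function(n) {
    tr <- synthetic_hjc_training(n = n, noise_sd = 2, seed = 77)
    m <- fit_hjc_regression(tr)
    truth_x <- c(-28, 0, -0.55)  # generating anthropometric rule
    sqrt(mean((m$x_coef - truth_x)^2))
  })
  expect_lt(rmse[2], rmse[1])
})

test_that("joint-centre prediction applies the regression and the GT plane rule", {
  L <- planar_pelvis_landmarks(gt_y = 25)
  fr <- build_anatomical_frames(L)
  # zero coefficients isolate the y-rule: GT 25 mm dorsal -> y = -25
  jc <- predict_joint_centres(L, fr, zero_hjc_regression())
  expect_equal(jc$hjc_in_pelvis, c(0, -25, 0), tolerance = 1e-9)
  expect_equal(jc$sjc_in_femur, c(0, 0, 0))
  # exact-linear model evaluated at width 40, length 100
  set.seed(121)
  w <- runif(8, 30, 50); l <- runif(8, 85, 115)
  m <- fit_hjc_regression(data.frame(
    width = w, length = l, hjc_x = -30 - 0.5 * w - 0.3 * l,
    hjc_z = -5 + 0.1 * w))
  L2 <- L
  L2["L_ISCHIAL_TUB", ] <- c(-sqrt(100^2 - 0), 0, -25)
  jc2 <- predict_joint_centres(L2, build_anatomical_frames(L2), m)
  dims <- pelvic_dimensions(L2)
  expect_equal(unname(dims["width"]), 40, tolerance = 1e-9)
  expect_equal(jc2$hjc_in_pelvis[1], -30 - 0.5 * 40 - 0.3 * dims[["length"]],
               tolerance = 1e-9)
  # dual expression consistency at the calibration pose
  h1 <- rt_apply(fr$pelvis, jc$hjc_in_pelvis)
  h2 <- rt_apply(fr$femur, jc$hjc_in_femur)
  expect_equal(h1, h2, tolerance = 1e-9)
})

test_that("reference joint centres come from the sphere and cylinder fits", {
  L <- ref_subject()$landmarks
  fr <- build_anatomical_frames(L)
  hip <- attr(L, "true_hip")
  stifle <- attr(L, "true_stifle")
  axis <- list(point = stifle, direction = fr$femur$R[, 3])
  clouds <- synthesize_bone_clouds(hip, axis, seed = 3)
  jc <- reference_joint_centres(clouds$femoral_head, clouds$condyles, fr)
  expect_equal(rt_apply(fr$pelvis, jc$hjc_in_pelvis), hip, tolerance = 1e-7,
               ignore_attr = TRUE)
  expect_equal(rt_apply(fr$femur, jc$hjc_in_femur), hip, tolerance = 1e-7,
               ignore_attr = TRUE)
  expect_lt(sqrt(sum((rt_apply(fr$femur, jc$sjc_in_femur) - stifle)^2)), 0.5)
  noisy <- synthesize_bone_clouds(hip, axis,
                                  params = list(noise_sd = 0.3, n_head = 2000,
                                                n_condyle = 2000), seed = 4)
  jcn <- reference_joint_centres(noisy$femoral_head, noisy$condyles, fr)
  expect_lt(sqrt(sum((rt_apply(fr$pelvis, jcn$hjc_in_pelvis) - hip)^2)), 0.2)
  expect_lt(sqrt(sum((rt_apply(fr$femur, jcn$sjc_in_femur) - stifle)^2)), 0.5)
})

test_that("model assembly enforces the dynamic marker convention", {
  sub <- ref_subject()
  model <- sub$model
  dyn <- lapply(model$templates, function(tm)
    intersect(rownames(tm), model$dynamic))
  expect_equal(lengths(dyn), c(pelvis = 4, femur = 4, tibia = 4))
  expect_false(any(c("MED_EPICONDYLE", "MED_MALLEOLUS") %in% model$dynamic))
  expect_true(all(model$weights == 1))
  # removing both thigh tracking markers leaves the femur underdetermined
  fr <- build_anatomical_frames(sub$landmarks)
  tmpl <- build_marker_templates(sub$landmarks, fr)
  jc <- predict_joint_centres(sub$landmarks, fr, default_hjc_regression())
  expect_error(
    assemble_model(fr, tmpl, jc,
                   dynamic = setdiff(dynamic_markers(),
                                     c("THIGH_TRACK_1", "THIGH_TRACK_2"))),
    "femur")
})
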