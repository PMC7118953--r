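test_that("Cardan z-x-y composition matches elementary matrices and inverts cleanly", {
  expect_equal(cardan_zxy_to_rotation(c(0, 0, 0)), diag(3))
  # right-hand rule about z: 90 deg flexion maps x onto y
  expect_equal(as.numeric(cardan_zxy_to_rotation(c(90, 0, 0)) %*% c(1, 0, 0)),
               c(0, 1, 0), tolerance = 1e-12)
  # oracle: the three elementary matrices written out entry by entry
  ang <- c(25, -10, 40) * pi / 180
  Rz <- rbind(c(cos(ang[1]), -sin(ang[1]), 0),
              c(sin(ang[1]), cos(ang[1]), 0),
              c(0, 0, 1))
  Rx <- rbind(c(1, 0, 0),
              c(0, cos(ang[2]), -sin(ang[2])),
              c(0, sin(ang[2]), cos(ang[2])))
  Ry <- rbind(c(cos(ang[3]), 0, sin(ang[3])),
              c(0, 1, 0),
              c(-sin(ang[3]), 0, cos(ang[3])))
  R <- cardan_zxy_to_rotation(c(25, -10, 40))
  expect_equal(R, Rz %*% Rx %*% Ry, tolerance = 1e-12)
  expect_equal(rotation_to_cardan_zxy(R), c(25, -10, 40), tolerance = 1e-9)
  expect_equal(rotation_to_cardan_zxy(diag(3)), c(0, 0, 0))
  expect_error(rotation_to_cardan_zxy(cardan_zxy_to_rotation(c(25, 90, 40))),
               "gimbal")
  expect_error(cardan_zxy_to_rotation(c(NA, 0, 0)), "finite")
})

test_that("decompose-compose round trip is exact away from gimbal lock", {
  set.seed(11)
  for (i in 1:1000) {
    R <- rand_rotation(beta_max = 85)
    R2 <- cardan_zxy_to_rotation(rotation_to_cardan_zxy(R))
    expect_lt(norm(R - R2, "F"), 1e-9)
  }
})

test_that("rigid transforms satisfy group axioms", {
  set.seed(21)
  a <- rigid_transform(rand_rotation(), rnorm(3, sd = 50))
  b <- rigid_transform(rand_rotation(), rnorm(3, sd = 50))
  p <- rnorm(3, sd = 100)
  expect_equal(rt_apply(rt_compose(a, b), p),
               rt_apply(a, rt_apply(b, p)), tolerance = 1e-9)
  id <- rt_compose(a, rt_inverse(a))
  expect_lt(norm(id$R - diag(3), "F"), 1e-9)
  expect_lt(max(abs(id$t)), 1e-9)
})

test_that("weighted rigid fit recovers exact motions and honors weights", {
  set.seed(31)
  P <- matrix(rnorm(18, sd = 40), 6, 3)
  g <- rigid_transform(rand_rotation(), c(12, -7, 30))
  Q <- rt_apply(g, P)
  fit <- weighted_rigid_fit(P, Q)
  expect_lt(norm(fit$R - g$R, "F"), 1e-10)
  expect_lt(max(abs(fit$t - g$t)), 1e-10)
  # zero weight excludes a corrupted marker exactly
  Qc <- Q
  Qc[4, ] <- Qc[4, ] + c(25, -10, 5)
  w <- c(1, 1, 1, 0, 1, 1)
  fit_w <- weighted_rigid_fit(P, Qc, w)
  fit_del <- weighted_rigid_fit(P[-4, ], Qc[-4, ])
  expect_equal(fit_w$R, fit_del$R, tolerance = 1e-12)
  expect_equal(fit_w$t, fit_del$t, tolerance = 1e-12)
  expect_error(weighted_rigid_fit(P[1:2, ], Q[1:2, ]), "3 points")
  line <- cbind(1:5, 2 * (1:5), -1 * (1:5))
  expect_error(weighted_rigid_fit(line, line), "collinear")
})

test_that("weighted rigid fit equals a multi-start nonlinear oracle under noise", {
  set.seed(41)
  for (case in 1:5) {
    P <- matrix(rnorm(18, sd = 40), 6, 3)
    g <- rigid_transform(rand_rotation(beta_max = 60), rnorm(3, sd = 30))
    Q <- rt_apply(g, P) + matrix(rnorm(18, sd = 1), 6, 3)
    w <- runif(6, 0.5, 2)
    fit <- weighted_rigid_fit(P, Q, w)
    orc <- oracle_rigid_fit(P, Q, w)
    expect_lt(abs(rigid_fit_cost(fit, P, Q, w) - orc$cost), 1e-6)
    expect_lt(rotation_angle_rad(fit$R, orc$R), 1e-5)
  }
})

test_that("weighted rigid fit is equivariant and attains the cost minimum", {
  set.seed(51)
  P <- matrix(rnorm(24, sd = 40), 8, 3)
  Q <- rt_apply(rigid_transform(rand_rotation(), c(5, 5, 5)), P) +
    matrix(rnorm(24, sd = 0.5), 8, 3)
  w <- runif(8, 0.2, 2)
  fit <- weighted_rigid_fit(P, Q, w)
  S <- rand_rotation()
  fit_S <- weighted_rigid_fit(P %*% t(S), Q %*% t(S), w)
  expect_equal(fit_S$R, S %*% fit$R %*% t(S), tolerance = 1e-9)
  expect_equal(fit_S$t, as.numeric(S %*% fit$t), tolerance = 1e-9)
  c_opt <- rigid_fit_cost(fit, P, Q, w)
  for (i in 1:100) {
    tf <- rigid_transform(rand_rotation(), rnorm(3, sd = 20))
    expect_lte(c_opt, rigid_fit_cost(tf, P, Q, w) + 1e-9)
  }
})

sphere_points <- function(n, centre, r) {
  u <- matrix(rnorm(3 * n), n, 3)
  u <- u / sqrt(rowSums(u^2))
  sweep(r * u, 2, centre, "+")
}

test_that("sphere fit is exact without noise and accurate under noise", {
  set.seed(61)
  P <- sphere_points(200, c(10, -5, 3), 12)
  fit <- fit_sphere(P)
  expect_equal(fit$centre, c(10, -5, 3), tolerance = 1e-9)
  expect_equal(fit$radius, 12, tolerance = 1e-9)
  expect_lt(fit$rms_residual, 1e-9)
  Pn <- sphere_points(2000, c(10, -5, 3), 12) +
    matrix(rnorm(6000, sd = 0.2), 2000, 3)
  fitn <- fit_sphere(Pn)
  expect_lt(sqrt(sum((fitn$centre - c(10, -5, 3))^2)), 0.1)
  flat <- cbind(rnorm(10), rnorm(10), 0)
  expect_error(fit_sphere(flat), "coplanar")
})

test_that("cylinder fit recovers axis, radius and mid-extent point", {
  set.seed(71)
  th <- runif(500, 0, 2 * pi)
  z <- runif(500, -20, 20)
  P <- cbind(15 * cos(th), 15 * sin(th), z)
  fit <- fit_cylinder(P, init_axis = c(0.1, 0.05, 1))
  expect_lt(min(sqrt(sum((fit$axis_direction - c(0, 0, 1))^2)),
                sqrt(sum((fit$axis_direction + c(0, 0, 1))^2))), 1e-8)
  expect_equal(fit$radius, 15, tolerance = 1e-9)
  expect_error(fit_cylinder(cbind(1:10, 1:10, 1:10)), "collinear")
  # condyle-like arcs about a known axis
  clouds <- synthesize_bone_clouds(
    c(0, 0, 0), list(point = c(3, -2, 5), direction = c(0.2, 0.1, 1)),
    params = list(noise_sd = 0.3), seed = 7)
  fitc <- fit_cylinder(clouds$condyles, init_axis = c(0.2, 0.1, 1))
  expect_lt(sqrt(sum((fitc$mid_axis_point - c(3, -2, 5))^2)), 0.5)
})

test_that("plane fit is total-least-squares with exact degenerate handling", {
  P4 <- rbind(c(0, 0, 0), c(10, 0, 0), c(0, 10, 0), c(10, 10, 0))
  fit <- fit_plane(P4)
  expect_lt(fit$rms_residual, 1e-12)
  expect_equal(abs(fit$normal[3]), 1, tolerance = 1e-12)
  expect_equal(plane_signed_distance(fit$point, fit), 0, tolerance = 1e-12)
  set.seed(81)
  Pn <- cbind(runif(100, -50, 50), runif(100, -50, 50), rnorm(100, sd = 0.1))
  fitn <- fit_plane(Pn)
  ang <- acos(min(1, abs(fitn$normal[3])))
  expect_lt(ang * 180 / pi, 0.5)
  expect_error(fit_plane(rbind(c(0, 0, 0), c(1, 1, 1))), "3 points")
})

test_that("geometric fit residuals are invariant under rigid motion of the cloud", {
  set.seed(91)
  P <- sphere_points(300, c(2, 1, 0), 9) + matrix(rnorm(900, sd = 0.3), 300, 3)
  g <- rigid_transform(rand_rotation(), c(40, -20, 15))
  f1 <- fit_sphere(P)
  f2 <- fit_sphere(rt_apply(g, P))
  expect_equal(f1$rms_residual, f2$rms_residual, tolerance = 1e-9)
  expect_equal(rt_apply(g, f1$centre), f2$centre, tolerance = 1e-6)
  th <- runif(300, 0, pi)
  C <- cbind(8 * cos(th), 8 * sin(th), runif(300, -10, 10)) +
    matrix(rnorm(900, sd = 0.2), 300, 3)
  c1 <- fit_cylinder(C, c(0, 0, 1))
  c2 <- fit_cylinder(rt_apply(g, C), as.numeric(g$R %*% c(0, 0, 1)))
  expect_equal(c1$rms_residual, c2$rms_residual, tolerance = 1e-9)
})
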