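#' Weighted rigid point-set registration (Procrustes)
#'
#' Finds the rigid transform `(R, t)` minimizing the weighted sum of squared
#' distances `sum_i w_i * ||R p_i + t - q_i||^2` between a marker template
#' and its observed positions, with point correspondence by row index. This
#' is the per-segment estimator behind single-body optimization: it rigidly
#' fits the calibration-time marker array to the measured one, so only the
#' non-rigid (array-deforming) part of soft tissue artefact is absorbed.
#'
#' The closed-form solution uses the SVD of the weighted cross-covariance
#' with a reflection guard: when the naive solution would be a reflection,
#' the singular direction with the smallest singular value is flipped.
#'
#' @param template n x 3 matrix of local/template points (mm).
#' @param observed n x 3 matrix of observed points (mm), row-matched.
#' @param weights optional length-n non-negative weights (default uniform).
#' @return a `rigid_transform` mapping template points onto observed points.
#' @export
weighted_rigid_fit <- function(template, observed, weights = NULL) {
  P <- as.matrix(template); Q <- as.matrix(observed)
  if (ncol(P) != 3 || ncol(Q) != 3 || nrow(P) != nrow(Q))
    stop("weighted_rigid_fit: point sets must be matched n x 3 matrices", call. = FALSE)
  n <- nrow(P)
  w <- if (is.null(weights)) rep(1, n) else as.numeric(weights)
  if (length(w) != n || any(!is.finite(w)) || any(w < 0))
    stop("weighted_rigid_fit: weights must be finite and non-negative", call. = FALSE)
  eff <- w > 0
  if (sum(eff) < 3)
    stop("weighted_rigid_fit: fewer than 3 points with positive weight", call. = FALSE)
  P <- P[eff, , drop = FALSE]; Q <- Q[eff, , drop = FALSE]; w <- w[eff]
  sw <- sum(w)
  pbar <- colSums(P * w) / sw
  qbar <- colSums(Q * w) / sw
  Pc <- sweep(P, 2, pbar); Qc <- sweep(Q, 2, qbar)
  # collinear template points leave a rotation about the line undetermined
  if (svd(Pc * sqrt(w))$d[2] < 1e-9 * max(1, max(abs(Pc))))
    stop("weighted_rigid_fit: effective points are collinear", call. = FALSE)
  H <- t(Pc * w) %*% Qc
  s <- svd(H)
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  rigid_transform(R, qbar - as.numeric(R %*% pbar), check = FALSE)
}

#' Weighted registration cost
#'
#' The objective value of [weighted_rigid_fit()] at an arbitrary transform;
#' exposed for diagnostics and optimality checks.
#'
#' @inheritParams weighted_rigid_fit
#' @param tf a `rigid_transform`.
#' @return the scalar weighted sum of squared residual distances (mm^2).
#' @export
rigid_fit_cost <- function(tf, template, observed, weights = NULL) {
  P <- as.matrix(template); Q <- as.matrix(observed)
  w <- if (is.null(weights)) rep(1, nrow(P)) else as.numeric(weights)
  r <- rt_apply(tf, P) - Q
  sum(w * rowSums(r^2))
}

fit_solver_control <- function() {
  minpack.lm::nls.lm.control(ftol = 1e-10, ptol = 1e-12, maxiter = 200)
}

#' Least-squares sphere fit
#'
#' Fits a sphere by minimizing the sum of squared orthogonal distances
#' `sum_i (||p_i - c|| - r)^2`. A linear algebraic fit provides the starting
#' point for the geometric (orthogonal-distance) refinement. Used to locate
#' the hip joint centre as the centre of the sphere best fitted to femoral
#' head surface points.
#'
#' @param points n x 3 matrix (mm), n >= 4, not coplanar.
#' @return a list with `centre` (mm), `radius` (mm) and `rms_residual` (mm).
#' @export
fit_sphere <- function(points) {
  P <- as.matrix(points)
  if (nrow(P) < 4) stop("fit_sphere: at least 4 points required", call. = FALSE)
  Pc <- sweep(P, 2, colMeans(P))
  if (min(svd(Pc)$d) < 1e-9 * max(1, max(abs(Pc))))
    stop("fit_sphere: points are (nearly) coplanar", call. = FALSE)
  # algebraic initializer: ||p||^2 = 2 c.p + (r^2 - ||c||^2)
  A <- cbind(2 * P, 1)
  b <- rowSums(P^2)
  beta <- qr.solve(A, b)
  c0 <- beta[1:3]
  r0 <- sqrt(max(beta[4] + sum(c0^2), .Machine$double.eps))
  res_fn <- function(par) sqrt(rowSums(sweep(P, 2, par[1:3])^2)) - par[4]
  fit <- minpack.lm::nls.lm(par = c(c0, r0), fn = res_fn,
                            control = fit_solver_control())
  par <- fit$par
  if (par[4] <= 0) stop("fit_sphere: degenerate (non-positive radius)", call. = FALSE)
  list(centre = as.numeric(par[1:3]), radius = par[4],
       rms_residual = sqrt(mean(res_fn(par)^2)))
}

#' Least-squares cylinder fit
#'
#' Fits an infinite circular cylinder by minimizing
#' `sum_i (d_i - r)^2` where `d_i` is the orthogonal distance of point `i`
#' from the axis. The axis direction is parameterized by spherical angles
#' and the axis anchor constrained to the plane through the data centroid
#' perpendicular to the current axis (removing the sliding redundancy).
#' Used to locate the stifle joint centre as the mid-extent axis point of
#' the cylinder best fitted to the femoral condyle surface; the fit reports
#' the projected extent of the data so that this "centroid" of an infinite
#' primitive is well defined.
#'
#' @param points n x 3 matrix (mm), n >= 6, not collinear.
#' @param init_axis non-zero length-3 starting axis direction.
#' @return list with `axis_point` (on the axis, at the perpendicular foot of
#'   the data centroid), `axis_direction` (unit vector), `radius` (mm),
#'   `axis_extent` (range of point projections onto the axis, mm, relative
#'   to `axis_point`), `mid_axis_point` (axis point at mid-extent, mm) and
#'   `rms_residual` (mm).
#' @export
fit_cylinder <- function(points, init_axis = c(0, 0, 1)) {
  P <- as.matrix(points)
  if (nrow(P) < 6) stop("fit_cylinder: at least 6 points required", call. = FALSE)
  a0 <- as.numeric(init_axis)
  if (sqrt(sum(a0^2)) < .Machine$double.eps)
    stop("fit_cylinder: init_axis must be non-zero", call. = FALSE)
  a0 <- a0 / sqrt(sum(a0^2))
  ctr <- colMeans(P)
  Pc <- sweep(P, 2, ctr)
  sv <- svd(Pc)$d
  if (sv[2] < 1e-9 * max(1, sv[1]))
    stop("fit_cylinder: points are collinear", call. = FALSE)

  axis_from_angles <- function(th, ph)
    c(sin(th) * cos(ph), sin(th) * sin(ph), cos(th))
  perp_basis <- function(a) {
    ref <- if (abs(a[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
    u <- ref - sum(ref * a) * a; u <- u / sqrt(sum(u^2))
    v <- c(a[2] * u[3] - a[3] * u[2], a[3] * u[1] - a[1] * u[3],
           a[1] * u[2] - a[2] * u[1])
    cbind(u, v)
  }
  th0 <- acos(max(-1, min(1, a0[3]))); ph0 <- atan2(a0[2], a0[1])
  dist_to_axis <- function(par) {
    a <- axis_from_angles(par[1], par[2])
    B <- perp_basis(a)
    p0 <- ctr + B %*% par[3:4]
    D <- sweep(P, 2, as.numeric(p0))
    proj <- D %*% a
    sqrt(pmax(rowSums(D^2) - proj^2, 0))
  }
  res_fn <- function(par) dist_to_axis(par) - par[5]
  r0 <- mean(dist_to_axis(c(th0, ph0, 0, 0, 0)))
  fit <- minpack.lm::nls.lm(par = c(th0, ph0, 0, 0, r0), fn = res_fn,
                            control = fit_solver_control())
  if (fit$info == 9)
    stop(sprintf("fit_cylinder: no convergence after %d iterations", fit$niter),
         call. = FALSE)
  par <- fit$par
  a <- axis_from_angles(par[1], par[2])
  B <- perp_basis(a)
  p0 <- as.numeric(ctr + B %*% par[3:4])
  proj <- as.numeric(sweep(P, 2, p0) %*% a)
  ext <- range(proj)
  list(axis_point = p0, axis_direction = a, radius = abs(par[5]),
       axis_extent = ext, mid_axis_point = p0 + mean(ext) * a,
       rms_residual = sqrt(mean(res_fn(par)^2)))
}

#' Total-least-squares plane fit
#'
#' Fits the plane minimizing the sum of squared orthogonal point-plane
#' distances; the normal is the smallest principal direction of the centered
#' point cloud. Used for the posterior pelvic plane through the four pelvic
#' landmarks.
#'
#' @param points n x 3 matrix (mm), n >= 3, non-collinear.
#' @return list with `point` (the centroid, on the plane), `normal`
#'   (unit vector) and `rms_residual` (mm).
#' @export
fit_plane <- function(points) {
  P <- as.matrix(points)
  if (nrow(P) < 3) stop("fit_plane: at least 3 points required", call. = FALSE)
  ctr <- colMeans(P)
  Pc <- sweep(P, 2, ctr)
  s <- svd(Pc)
  if (s$d[2] < 1e-9 * max(1, s$d[1]))
    stop("fit_plane: points are collinear", call. = FALSE)
  n <- s$v[, 3]
  list(point = ctr, normal = n,
       rms_residual = sqrt(mean(as.numeric(Pc %*% n)^2)))
}

#' Signed distance of a point from a plane
#'
#' @param p length-3 point (mm).
#' @param plane a plane fit from [fit_plane()].
#' @return signed orthogonal distance (mm), positive on the side of the
#'   plane normal.
#' @export
plane_signed_distance <- function(p, plane) {
  sum((as.numeric(p) - plane$point) * plane$normal)
}
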