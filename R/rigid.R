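#' Rigid transforms and Cardan z-x-y angles
#'
#' A rigid transform is a proper rotation plus a translation, used throughout
#' the package to express the pose of a segment's anatomical frame in the
#' laboratory frame. Units are millimetres for translations and degrees for
#' the Cardan angle interface.
#'
#' @name rigid-transforms
NULL

DEG2RAD <- pi / 180
RAD2DEG <- 180 / pi

#' Create a rigid transform
#'
#' @param R 3x3 proper rotation matrix (orthonormal, determinant +1).
#' @param t translation, length-3 numeric (mm).
#' @param check validate the rotation matrix (default TRUE).
#' @return an object of class `rigid_transform` with elements `R` and `t`.
#' @export
rigid_transform <- function(R = diag(3), t = c(0, 0, 0), check = TRUE) {
  R <- matrix(as.numeric(R), 3, 3)
  t <- as.numeric(t)
  if (length(t) != 3 || !all(is.finite(t)) || !all(is.finite(R)))
    stop("rigid_transform: non-finite or wrongly sized input", call. = FALSE)
  if (check) assert_rotation(R)
  structure(list(R = R, t = t), class = "rigid_transform")
}

assert_rotation <- function(R, tol = 1e-6) {
  if (max(abs(crossprod(R) - diag(3))) > tol || abs(det(R) - 1) > tol)
    stop("not a proper rotation matrix", call. = FALSE)
  invisible(R)
}

#' @export
print.rigid_transform <- function(x, ...) {
  cat("<rigid_transform>\n")
  m <- cbind(x$R, x$t)
  dimnames(m) <- list(NULL, c("R1", "R2", "R3", "t (mm)"))
  print(round(m, 6))
  invisible(x)
}

#' Compose two rigid transforms
#'
#' `rt_compose(a, b)` returns the transform equivalent to applying `b` first
#' and then `a` (matrix convention: `a %*% b`).
#'
#' @param a,b `rigid_transform` objects.
#' @return a `rigid_transform`.
#' @export
rt_compose <- function(a, b) {
  rigid_transform(a$R %*% b$R, as.numeric(a$R %*% b$t) + a$t, check = FALSE)
}

#' Invert a rigid transform
#' @param a a `rigid_transform`.
#' @return the inverse `rigid_transform`.
#' @export
rt_inverse <- function(a) {
  Rt <- t(a$R)
  rigid_transform(Rt, as.numeric(-Rt %*% a$t), check = FALSE)
}

#' Apply a rigid transform to points
#'
#' @param a a `rigid_transform`.
#' @param pts either a length-3 vector or an n x 3 matrix of points (mm).
#' @return transformed points with the same shape as the input.
#' @export
rt_apply <- function(a, pts) {
  if (is.null(dim(pts))) return(as.numeric(a$R %*% as.numeric(pts)) + a$t)
  pts <- as.matrix(pts)
  sweep(pts %*% t(a$R), 2, a$t, "+")
}

elem_rot <- function(axis, angle_rad) {
  c1 <- cos(angle_rad); s1 <- sin(angle_rad)
  switch(axis,
    x = matrix(c(1, 0, 0, 0, c1, s1, 0, -s1, c1), 3, 3),
    y = matrix(c(c1, 0, -s1, 0, 1, 0, s1, 0, c1), 3, 3),
    z = matrix(c(c1, s1, 0, -s1, c1, 0, 0, 0, 1), 3, 3))
}

#' Cardan z-x-y angles to rotation matrix
#'
#' Composes the intrinsic (body-fixed) z-x-y sequence
#' `Rz(alpha) %*% Rx(beta) %*% Ry(gamma)` used project-wide for joint
#' rotations: `alpha` flexion/extension, `beta` adduction/abduction,
#' `gamma` internal/external rotation.
#'
#' @param angles_deg numeric length 3: flexion/extension,
#'   adduction/abduction, internal/external rotation, in degrees.
#' @return a 3x3 proper rotation matrix.
#' @seealso [rotation_to_cardan_zxy()]
#' @export
cardan_zxy_to_rotation <- function(angles_deg) {
  if (length(angles_deg) != 3 || !all(is.finite(angles_deg)))
    stop("cardan_zxy_to_rotation: angles must be 3 finite numbers", call. = FALSE)
  a <- angles_deg * DEG2RAD
  elem_rot("z", a[1]) %*% elem_rot("x", a[2]) %*% elem_rot("y", a[3])
}

#' Rotation matrix to Cardan z-x-y angles
#'
#' Inverts [cardan_zxy_to_rotation()]. The middle angle (adduction/abduction)
#' is returned in \[-90, 90\] degrees. Within 1e-8 of gimbal lock
#' (`|sin(beta)| = 1`) the decomposition is ill-posed and an error is raised
#' rather than silently fixing a convention; canine gait keeps all joints far
#' from this configuration.
#'
#' @param R a 3x3 proper rotation matrix.
#' @return numeric length 3 (degrees): flexion/extension,
#'   adduction/abduction, internal/external rotation.
#' @export
rotation_to_cardan_zxy <- function(R) {
  assert_rotation(R)
  sb <- max(-1, min(1, R[3, 2]))
  if (abs(abs(sb) - 1) < 1e-8)
    stop("gimbal lock: adduction/abduction at +/-90 degrees", call. = FALSE)
  c(atan2(-R[1, 2], R[2, 2]),
    asin(sb),
    atan2(-R[3, 1], R[3, 3])) * RAD2DEG
}
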