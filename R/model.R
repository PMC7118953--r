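#' Marker conventions for the canine pelvic limb
#'
#' The calibration marker set comprises 12 anatomical landmarks, two thigh
#' tracking markers and one foot marker. Medial-side markers
#' (`MED_EPICONDYLE`, `MED_MALLEOLUS`) are present only during the standing
#' calibration and are removed for dynamic trials, leaving four tracking
#' markers per segment. The foot marker serves paw-contact detection only
#' and belongs to no rigid segment.
#'
#' @return `landmark_names()`: character vector of the 15 canonical marker
#'   names. `segment_markers()`: named list giving the marker-to-segment
#'   assignment. `dynamic_markers()`: markers retained in dynamic trials.
#' @export
landmark_names <- function() {
  c("L_ILIAC_CREST", "R_ILIAC_CREST", "L_ISCHIAL_TUB", "R_ISCHIAL_TUB",
    "GT", "LAT_EPICONDYLE", "MED_EPICONDYLE",
    "FIB_HEAD", "PROX_TIB_CREST", "DIST_TIB_CREST",
    "LAT_MALLEOLUS", "MED_MALLEOLUS",
    "THIGH_TRACK_1", "THIGH_TRACK_2", "FOOT")
}

#' @rdname landmark_names
#' @export
segment_markers <- function() {
  list(
    pelvis = c("L_ILIAC_CREST", "R_ILIAC_CREST", "L_ISCHIAL_TUB", "R_ISCHIAL_TUB"),
    femur  = c("GT", "LAT_EPICONDYLE", "MED_EPICONDYLE",
               "THIGH_TRACK_1", "THIGH_TRACK_2"),
    tibia  = c("FIB_HEAD", "PROX_TIB_CREST", "DIST_TIB_CREST",
               "LAT_MALLEOLUS", "MED_MALLEOLUS"))
}

MEDIAL_MARKERS <- c("MED_EPICONDYLE", "MED_MALLEOLUS")

#' @rdname landmark_names
#' @export
dynamic_markers <- function() {
  setdiff(unlist(segment_markers(), use.names = FALSE), MEDIAL_MARKERS)
}

as_landmark_matrix <- function(landmarks) {
  if (is.list(landmarks) && !is.data.frame(landmarks))
    landmarks <- do.call(rbind, landmarks)
  L <- as.matrix(landmarks)
  if (ncol(L) != 3 || is.null(rownames(L)))
    stop("landmarks must be a named n x 3 matrix or named list of xyz triples",
         call. = FALSE)
  if (anyDuplicated(rownames(L)))
    stop("duplicate landmark names", call. = FALSE)
  storage.mode(L) <- "double"
  L
}

need_landmarks <- function(L, names) {
  miss <- setdiff(names, rownames(L))
  if (length(miss))
    stop("missing landmark(s): ", paste(miss, collapse = ", "), call. = FALSE)
  L[names, , drop = FALSE]
}

unit <- function(v) {
  n <- sqrt(sum(v^2))
  if (n < 1e-12) stop("degenerate (zero-length) axis direction", call. = FALSE)
  v / n
}

orthounit <- function(v, against) unit(v - sum(v * against) * against)

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

frame_from_axes <- function(x = NULL, y = NULL, z = NULL, origin) {
  R <- cbind(x, y, z)
  rigid_transform(R, origin)
}

#' Build anatomical frames from a standing calibration
#'
#' Constructs the pelvis, femur and tibia anatomical frames (AFs) from the
#' calibration landmark positions. All frames follow the same axis
#' convention for a right limb: x cranial, y proximal, z lateral,
#' right-handed.
#'
#' \describe{
#'   \item{pelvis}{origin at the midpoint of the iliac crests; x from the
#'     mid-ischial-tuberosity point towards the mid-iliac-crest point; z
#'     along the left-to-right iliac crest direction orthogonalized against
#'     x; y = z cross x.}
#'   \item{femur}{origin at the midpoint of the femoral epicondyles; y
#'     towards the greater trochanter (GT); z lateral in the plane spanned
#'     by the origin, GT and the lateral epicondyle; x = y cross z.}
#'   \item{tibia}{origin at the midpoint of the malleoli; y towards the
#'     midpoint of the fibular head and proximal tibial crest; z lateral in
#'     the plane containing the lateral malleolus; x = y cross z.}
#' }
#'
#' @param landmarks named n x 3 matrix (or named list of xyz triples) of
#'   calibration marker positions in the laboratory frame (mm).
#' @return named list of `rigid_transform` poses (`pelvis`, `femur`,
#'   `tibia`), each expressing the AF in the laboratory frame.
#' @export
build_anatomical_frames <- function(landmarks) {
  L <- as_landmark_matrix(landmarks)

  pl <- need_landmarks(L, c("L_ILIAC_CREST", "R_ILIAC_CREST",
                            "L_ISCHIAL_TUB", "R_ISCHIAL_TUB"))
  mid_iliac <- (pl["L_ILIAC_CREST", ] + pl["R_ILIAC_CREST", ]) / 2
  mid_isch  <- (pl["L_ISCHIAL_TUB", ] + pl["R_ISCHIAL_TUB", ]) / 2
  px <- unit(mid_iliac - mid_isch)
  pz <- orthounit(pl["R_ILIAC_CREST", ] - pl["L_ILIAC_CREST", ], px)
  pelvis <- frame_from_axes(x = px, y = cross3(pz, px), z = pz,
                            origin = mid_iliac)

  fl <- need_landmarks(L, c("GT", "LAT_EPICONDYLE", "MED_EPICONDYLE"))
  f_origin <- (fl["LAT_EPICONDYLE", ] + fl["MED_EPICONDYLE", ]) / 2
  fy <- unit(fl["GT", ] - f_origin)
  fz <- orthounit(fl["LAT_EPICONDYLE", ] - f_origin, fy)
  femur <- frame_from_axes(x = cross3(fy, fz), y = fy, z = fz,
                           origin = f_origin)

  tl <- need_landmarks(L, c("FIB_HEAD", "PROX_TIB_CREST",
                            "LAT_MALLEOLUS", "MED_MALLEOLUS"))
  t_origin <- (tl["LAT_MALLEOLUS", ] + tl["MED_MALLEOLUS", ]) / 2
  ty <- unit((tl["FIB_HEAD", ] + tl["PROX_TIB_CREST", ]) / 2 - t_origin)
  tz <- orthounit(tl["LAT_MALLEOLUS", ] - t_origin, ty)
  tibia <- frame_from_axes(x = cross3(ty, tz), y = ty, z = tz,
                           origin = t_origin)

  list(pelvis = pelvis, femur = femur, tibia = tibia)
}

#' Extract per-segment marker templates
#'
#' Expresses each segment's calibration markers in its anatomical frame,
#' producing the time-invariant "marker templates" used by both tracking
#' methods.
#'
#' @inheritParams build_anatomical_frames
#' @param frames anatomical frames from [build_anatomical_frames()].
#' @return named list (`pelvis`, `femur`, `tibia`) of m x 3 matrices of
#'   local marker coordinates (mm), rownames = marker names.
#' @export
build_marker_templates <- function(landmarks, frames) {
  L <- as_landmark_matrix(landmarks)
  seg <- segment_markers()
  out <- lapply(names(seg), function(s) {
    pts <- need_landmarks(L, seg[[s]])
    loc <- rt_apply(rt_inverse(frames[[s]]), pts)
    dimnames(loc) <- list(seg[[s]], c("x", "y", "z"))
    loc
  })
  names(out) <- names(seg)
  out
}

#' Pelvic width and length from calibration markers
#'
#' Width is the distance between the bilateral iliac crest markers; length
#' the distance between the midpoint of the iliac crests and the midpoint
#' of the ischial tuberosities. These are the two predictors of the hip
#' joint centre regression.
#'
#' @inheritParams build_anatomical_frames
#' @return named numeric: `width`, `length` (mm).
#' @export
pelvic_dimensions <- function(landmarks) {
  L <- as_landmark_matrix(landmarks)
  pl <- need_landmarks(L, c("L_ILIAC_CREST", "R_ILIAC_CREST",
                            "L_ISCHIAL_TUB", "R_ISCHIAL_TUB"))
  mid_iliac <- (pl["L_ILIAC_CREST", ] + pl["R_ILIAC_CREST", ]) / 2
  mid_isch  <- (pl["L_ISCHIAL_TUB", ] + pl["R_ISCHIAL_TUB", ]) / 2
  c(width = sqrt(sum((pl["R_ILIAC_CREST", ] - pl["L_ILIAC_CREST", ])^2)),
    length = sqrt(sum((mid_iliac - mid_isch)^2)))
}

#' Posterior pelvic plane
#'
#' Total-least-squares plane through the four pelvic landmarks (bilateral
#' iliac crests and ischial tuberosities), with the normal oriented towards
#' the dorsal (proximal, +y) side of the pelvic frame.
#'
#' @inheritParams build_anatomical_frames
#' @param frames anatomical frames (used only to orient the normal).
#' @return a plane fit as from [fit_plane()].
#' @export
posterior_pelvic_plane <- function(landmarks, frames = build_anatomical_frames(landmarks)) {
  L <- as_landmark_matrix(landmarks)
  pts <- need_landmarks(L, segment_markers()$pelvis)
  pl <- fit_plane(pts)
  if (sum(pl$normal * frames$pelvis$R[, 2]) < 0) pl$normal <- -pl$normal
  pl
}

#' Fit the hip joint centre regression
#'
#' Ordinary least squares regression of the hip joint centre's
#' cranio-caudal (x) and latero-medial (z) pelvic-frame coordinates on
#' pelvic width and pelvic length, fitted independently per coordinate.
#' Intended to be trained on bone-derived reference joint centres from a
#' cohort of subjects; each coordinate equation has two predictors and
#' three parameters (intercept plus two slopes).
#'
#' @param training data.frame with columns `width`, `length` (mm) and
#'   `hjc_x`, `hjc_z` (reference hip joint centre pelvic-frame coordinates,
#'   mm). At least 3 rows with a full-rank design.
#' @return object of class `hjc_regression`: coefficient vectors `x_coef`
#'   and `z_coef` (named intercept/width/length), residual RMS per
#'   coordinate, and `n_train`.
#' @export
fit_hjc_regression <- function(training) {
  training <- as.data.frame(training)
  req <- c("width", "length", "hjc_x", "hjc_z")
  miss <- setdiff(req, names(training))
  if (length(miss))
    stop("fit_hjc_regression: missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  n <- nrow(training)
  X <- cbind(intercept = 1, width = training$width, length = training$length)
  if (n < 3 || qr(X)$rank < 3)
    stop("fit_hjc_regression: rank-deficient design (need >= 3 subjects with varying width/length)",
         call. = FALSE)
  fit1 <- lm.fit(X, training$hjc_x)
  fit2 <- lm.fit(X, training$hjc_z)
  structure(list(
    x_coef = stats::setNames(fit1$coefficients, c("intercept", "width", "length")),
    z_coef = stats::setNames(fit2$coefficients, c("intercept", "width", "length")),
    rms = c(x = sqrt(mean(fit1$residuals^2)), z = sqrt(mean(fit2$residuals^2))),
    n_train = n), class = "hjc_regression")
}

#' @export
print.hjc_regression <- function(x, ...) {
  cat("<hjc_regression> fitted on", x$n_train, "subjects\n")
  cat("  x =", sprintf("%+.3f %+.4f*width %+.4f*length", x$x_coef[1], x$x_coef[2], x$x_coef[3]),
      sprintf("(RMS %.2f mm)\n", x$rms["x"]))
  cat("  z =", sprintf("%+.3f %+.4f*width %+.4f*length", x$z_coef[1], x$z_coef[2], x$z_coef[3]),
      sprintf("(RMS %.2f mm)\n", x$rms["z"]))
  invisible(x)
}

#' Predict hip and stifle joint centres from landmarks
#'
#' The hip joint centre (HJC) x and z pelvic-frame coordinates come from
#' the regression model evaluated at the subject's pelvic width and length;
#' its y coordinate is minus the orthogonal distance of the greater
#' trochanter marker from the posterior pelvic plane, placing the HJC
#' distal to the plane. The stifle joint centre (SJC) is the origin of the
#' femoral anatomical frame. Each centre is expressed in both adjacent
#' segment frames through the calibration poses.
#'
#' @inheritParams build_anatomical_frames
#' @param frames anatomical frames from [build_anatomical_frames()].
#' @param model an `hjc_regression` model.
#' @return object of class `joint_centres`: `hjc_in_pelvis`,
#'   `hjc_in_femur`, `sjc_in_femur`, `sjc_in_tibia` (mm, local frames).
#' @export
predict_joint_centres <- function(landmarks, frames, model) {
  if (!inherits(model, "hjc_regression"))
    stop("model must be an hjc_regression", call. = FALSE)
  L <- as_landmark_matrix(landmarks)
  dims <- pelvic_dimensions(L)
  pred <- c(1, dims["width"], dims["length"])
  hjc_x <- sum(model$x_coef * pred)
  hjc_z <- sum(model$z_coef * pred)
  gt <- need_landmarks(L, "GT")[1, ]
  d <- plane_signed_distance(gt, posterior_pelvic_plane(L, frames))
  if (abs(d) < 1e-9)
    warning("GT lies on the posterior pelvic plane; HJC y-coordinate is 0")
  hjc_pelvis <- c(hjc_x, -abs(d), hjc_z)
  hjc_lab <- rt_apply(frames$pelvis, hjc_pelvis)
  sjc_femur <- c(0, 0, 0)
  sjc_lab <- rt_apply(frames$femur, sjc_femur)
  structure(list(
    hjc_in_pelvis = hjc_pelvis,
    hjc_in_femur = rt_apply(rt_inverse(frames$femur), hjc_lab),
    sjc_in_femur = sjc_femur,
    sjc_in_tibia = rt_apply(rt_inverse(frames$tibia), sjc_lab)),
    class = "joint_centres")
}

#' Reference joint centres from bone surface point clouds
#'
#' The reference hip joint centre is the centre of the sphere best fitted
#' to femoral head surface points; the reference stifle joint centre is the
#' mid-extent axis point of the cylinder best fitted to the bilateral
#' femoral condyle surface points. Clouds are given in the laboratory frame
#' at the calibration pose; both centres are re-expressed in the two
#' adjacent anatomical frames.
#'
#' @param femoral_head_cloud n x 3 matrix of femoral head surface points (mm).
#' @param condyle_cloud n x 3 matrix of condyle surface points (mm).
#' @param frames anatomical frames from [build_anatomical_frames()].
#' @param init_axis starting axis for the condyle cylinder fit; defaults to
#'   the femoral z (flexion) axis.
#' @return a `joint_centres` object (see [predict_joint_centres()]).
#' @export
reference_joint_centres <- function(femoral_head_cloud, condyle_cloud, frames,
                                    init_axis = frames$femur$R[, 3]) {
  hjc_lab <- fit_sphere(femoral_head_cloud)$centre
  sjc_lab <- fit_cylinder(condyle_cloud, init_axis)$mid_axis_point
  structure(list(
    hjc_in_pelvis = rt_apply(rt_inverse(frames$pelvis), hjc_lab),
    hjc_in_femur = rt_apply(rt_inverse(frames$femur), hjc_lab),
    sjc_in_femur = rt_apply(rt_inverse(frames$femur), sjc_lab),
    sjc_in_tibia = rt_apply(rt_inverse(frames$tibia), sjc_lab)),
    class = "joint_centres")
}

#' Assemble the subject-specific multibody model
#'
#' Validates and bundles the calibration frames, marker templates, joint
#' centres, per-marker weights and the dynamic-trial marker list into the
#' model used by [so_track()] and [mko_track()]. Medial markers are
#' excluded from the dynamic set (they are removed after calibration);
#' every segment must retain at least three dynamic markers.
#'
#' @param frames anatomical frames at calibration.
#' @param templates marker templates from [build_marker_templates()].
#' @param centres a `joint_centres` object.
#' @param weights optional named per-marker weights (default 1 for every
#'   dynamic marker).
#' @param dynamic named character vector of dynamic-trial markers; defaults
#'   to all segment markers minus the medial ones.
#' @return object of class `multibody_model`.
#' @export
assemble_model <- function(frames, templates, centres, weights = NULL,
                           dynamic = dynamic_markers()) {
  seg <- segment_markers()
  for (s in names(seg)) {
    nd <- sum(dynamic %in% rownames(templates[[s]]))
    if (nd < 3)
      stop(sprintf("segment '%s' has %d dynamic markers; at least 3 required", s, nd),
           call. = FALSE)
  }
  # joint-centre dual-expression consistency at the calibration pose
  gap_h <- rt_apply(frames$pelvis, centres$hjc_in_pelvis) -
           rt_apply(frames$femur, centres$hjc_in_femur)
  gap_s <- rt_apply(frames$femur, centres$sjc_in_femur) -
           rt_apply(frames$tibia, centres$sjc_in_tibia)
  if (max(abs(c(gap_h, gap_s))) > 1e-6)
    stop("joint centres are inconsistent with the calibration poses", call. = FALSE)
  if (is.null(weights)) {
    weights <- stats::setNames(rep(1, length(dynamic)), dynamic)
  } else {
    if (is.null(names(weights)) || any(!is.finite(weights)) || any(weights < 0))
      stop("weights must be a named non-negative numeric vector", call. = FALSE)
    w <- stats::setNames(rep(1, length(dynamic)), dynamic)
    w[intersect(names(weights), dynamic)] <-
      weights[intersect(names(weights), dynamic)]
    weights <- w
  }
  for (s in names(seg)) {
    ws <- weights[intersect(dynamic, rownames(templates[[s]]))]
    if (!any(ws > 0))
      stop(sprintf("segment '%s' has no positive-weight dynamic marker", s),
           call. = FALSE)
  }
  structure(list(frames = frames, templates = templates, centres = centres,
                 weights = weights, dynamic = dynamic),
            class = "multibody_model")
}

#' @export
print.multibody_model <- function(x, ...) {
  cat("<multibody_model> pelvis/femur/tibia chain, spherical hip and stifle joints\n")
  for (s in names(x$templates)) {
    dyn <- intersect(x$dynamic, rownames(x$templates[[s]]))
    cat(sprintf("  %-6s %d markers (%d dynamic)\n", s,
                nrow(x$templates[[s]]), length(dyn)))
  }
  cat(sprintf("  HJC (pelvis frame): %s mm\n",
              paste(sprintf("%.1f", x$centres$hjc_in_pelvis), collapse = ", ")))
  cat(sprintf("  SJC (femur frame):  %s mm\n",
              paste(sprintf("%.1f", x$centres$sjc_in_femur), collapse = ", ")))
  invisible(x)
}

#' Build a complete model from a calibration in one call
#'
#' Convenience wrapper chaining [build_anatomical_frames()],
#' [build_marker_templates()], [predict_joint_centres()] and
#' [assemble_model()].
#'
#' @inheritParams build_anatomical_frames
#' @param hjc_model an `hjc_regression`; defaults to
#'   [default_hjc_regression()].
#' @param weights optional named per-marker weights.
#' @return a `multibody_model`.
#' @export
calibrate_model <- function(landmarks, hjc_model = default_hjc_regression(),
                            weights = NULL) {
  frames <- build_anatomical_frames(landmarks)
  templates <- build_marker_templates(landmarks, frames)
  centres <- predict_joint_centres(landmarks, frames, hjc_model)
  assemble_model(frames, templates, centres, weights)
}
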