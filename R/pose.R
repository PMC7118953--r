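#' Marker trajectory container
#'
#' Time-indexed named marker positions with per-frame visibility. Missing
#' samples (occlusions) are stored as `NA` coordinates with
#' `visible = FALSE`.
#'
#' @param xyz numeric array `[n_frames, 3, n_markers]` (mm) with marker
#'   names as the third dimnames; `NA` rows mark invisible samples.
#' @param rate_hz sampling rate (Hz).
#' @param time optional time vector (s); defaults to `(0:(n-1))/rate_hz`.
#' @return object of class `marker_trajectories`.
#' @export
marker_trajectories <- function(xyz, rate_hz, time = NULL) {
  if (length(dim(xyz)) != 3 || dim(xyz)[2] != 3 || is.null(dimnames(xyz)[[3]]))
    stop("xyz must be an [n, 3, m] array with marker names", call. = FALSE)
  if (rate_hz <= 0) stop("rate_hz must be positive", call. = FALSE)
  n <- dim(xyz)[1]
  if (is.null(time)) time <- (seq_len(n) - 1) / rate_hz
  if (length(time) != n || is.unsorted(time, strictly = TRUE))
    stop("time must be strictly increasing with one entry per frame", call. = FALSE)
  visible <- t(apply(xyz, 1, function(fr) colSums(is.finite(fr)) == 3))
  if (n == 1) visible <- matrix(visible, 1)
  colnames(visible) <- dimnames(xyz)[[3]]
  structure(list(xyz = xyz, rate_hz = rate_hz, time = time,
                 markers = dimnames(xyz)[[3]], visible = visible,
                 n_frames = n),
            class = "marker_trajectories")
}

#' @export
print.marker_trajectories <- function(x, ...) {
  cat(sprintf("<marker_trajectories> %d frames @ %g Hz, %d markers (%.1f s)\n",
              x$n_frames, x$rate_hz, length(x$markers), diff(range(x$time))))
  cat("  markers:", paste(x$markers, collapse = ", "), "\n")
  invisible(x)
}

frame_markers <- function(traj, k) {
  m <- t(traj$xyz[k, , ])
  colnames(m) <- c("x", "y", "z")
  m
}

#' Forward kinematics of the 12-DOF pelvic limb chain
#'
#' Maps a 12-DOF vector to the laboratory poses of the three segments.
#' DOFs 1-3 are the pelvis translation (mm), 4-6 the pelvis orientation
#' (Cardan z-x-y, deg), 7-9 the femur rotation about the hip joint centre
#' relative to the pelvis, and 10-12 the tibia rotation about the stifle
#' joint centre relative to the femur (both Cardan z-x-y, deg). The
#' spherical hip and stifle constraints are satisfied by construction:
#' both segments of each joint place the shared centre at the same
#' laboratory point.
#'
#' @param model a `multibody_model`.
#' @param q numeric length-12 DOF vector.
#' @return named list of `rigid_transform` poses (`pelvis`, `femur`,
#'   `tibia`).
#' @export
fk_poses <- function(model, q) {
  if (length(q) != 12 || !all(is.finite(q)))
    stop("fk_poses: q must be 12 finite numbers", call. = FALSE)
  cn <- model$centres
  Rp <- cardan_zxy_to_rotation(q[4:6])
  pelvis <- rigid_transform(Rp, q[1:3], check = FALSE)
  hjc_lab <- rt_apply(pelvis, cn$hjc_in_pelvis)
  Rf <- Rp %*% cardan_zxy_to_rotation(q[7:9])
  femur <- rigid_transform(Rf, hjc_lab - as.numeric(Rf %*% cn$hjc_in_femur),
                           check = FALSE)
  sjc_lab <- rt_apply(femur, cn$sjc_in_femur)
  Rt <- Rf %*% cardan_zxy_to_rotation(q[10:12])
  tibia <- rigid_transform(Rt, sjc_lab - as.numeric(Rt %*% cn$sjc_in_tibia),
                           check = FALSE)
  list(pelvis = pelvis, femur = femur, tibia = tibia)
}

#' Project per-segment poses onto the 12-DOF chain
#'
#' Converts independent segment poses (e.g. a single-body-optimization
#' solution) to the nearest chain coordinates: the pelvis DOFs are taken
#' directly and the joint rotations are the Cardan decompositions of the
#' relative rotations. Joint-centre translation gaps present in the input
#' poses are absorbed by the chain construction.
#'
#' @param poses named list of `rigid_transform` (`pelvis`, `femur`,
#'   `tibia`).
#' @return numeric length-12 DOF vector.
#' @export
poses_to_dof <- function(poses) {
  c(poses$pelvis$t,
    rotation_to_cardan_zxy(poses$pelvis$R),
    rotation_to_cardan_zxy(t(poses$pelvis$R) %*% poses$femur$R),
    rotation_to_cardan_zxy(t(poses$femur$R) %*% poses$tibia$R))
}

segment_of_marker <- function() {
  seg <- segment_markers()
  stats::setNames(rep(names(seg), lengths(seg)), unlist(seg, use.names = FALSE))
}

#' Single-body optimization (SO) tracking
#'
#' Tracks each segment independently: for every frame, the segment's
#' marker template is rigidly fitted (weighted least squares) to the
#' visible dynamic markers of that segment. No joint constraint is
#' imposed, so SO absorbs only the non-rigid part of soft tissue artefact;
#' an artefact that moves a whole marker cluster rigidly passes straight
#' into the estimated pose. A segment-frame with fewer than three visible
#' markers is flagged invalid, never extrapolated.
#'
#' @param trajectories a `marker_trajectories`.
#' @param model a `multibody_model`.
#' @param weights optional named per-marker weights (default: model
#'   weights).
#' @return object of class `tracking_result`: `poses` (per-frame named
#'   pose lists; invalid segments are `NULL`), `valid` (frames x segments
#'   logical), `residual` (weighted RMS marker distance per frame, mm),
#'   `method = "so"`.
#' @export
so_track <- function(trajectories, model, weights = NULL) {
  w_all <- if (is.null(weights)) model$weights else weights
  seg_names <- c("pelvis", "femur", "tibia")
  n <- trajectories$n_frames
  poses <- vector("list", n)
  valid <- matrix(FALSE, n, 3, dimnames = list(NULL, seg_names))
  residual <- rep(NA_real_, n)
  for (k in seq_len(n)) {
    obs <- frame_markers(trajectories, k)
    pk <- list(pelvis = NULL, femur = NULL, tibia = NULL)
    sq_sum <- 0; w_sum <- 0
    for (s in seg_names) {
      tmpl <- model$templates[[s]]
      dyn <- intersect(intersect(rownames(tmpl), model$dynamic),
                       trajectories$markers)
      vis <- dyn[trajectories$visible[k, dyn]]
      w <- w_all[vis]
      if (length(vis[w > 0]) >= 3) {
        fit <- try(weighted_rigid_fit(tmpl[vis, , drop = FALSE],
                                      obs[vis, , drop = FALSE], w),
                   silent = TRUE)
        if (!inherits(fit, "try-error")) {
          pk[[s]] <- fit
          valid[k, s] <- TRUE
          r2 <- rowSums((rt_apply(fit, tmpl[vis, , drop = FALSE]) -
                           obs[vis, , drop = FALSE])^2)
          sq_sum <- sq_sum + sum(w * r2)
          w_sum <- w_sum + sum(w)
        }
      }
    }
    poses[[k]] <- pk
    if (w_sum > 0) residual[k] <- sqrt(sq_sum / w_sum)
  }
  structure(list(method = "so", poses = poses, valid = valid,
                 residual = residual, time = trajectories$time,
                 rate_hz = trajectories$rate_hz),
            class = "tracking_result")
}

mko_residual_fn <- function(model, obs, vis_markers, sqw, seg_of) {
  tmpl_rows <- lapply(c("pelvis", "femur", "tibia"), function(s) {
    mk <- vis_markers[seg_of[vis_markers] == s]
    model$templates[[s]][mk, , drop = FALSE]
  })
  names(tmpl_rows) <- c("pelvis", "femur", "tibia")
  obs_rows <- obs[unlist(lapply(tmpl_rows, rownames)), , drop = FALSE]
  sqw_rows <- sqw[rownames(obs_rows)]
  function(q) {
    poses <- fk_poses(model, q)
    pred <- rbind(rt_apply(poses$pelvis, tmpl_rows$pelvis),
                  rt_apply(poses$femur, tmpl_rows$femur),
                  rt_apply(poses$tibia, tmpl_rows$tibia))
    as.numeric((pred - obs_rows) * sqw_rows)
  }
}

#' Multibody kinematics optimization for a single frame
#'
#' Minimizes the weighted sum of squared distances between
#' model-determined and measured marker positions over the 12 chain DOFs,
#' using the Levenberg-Marquardt algorithm. The spherical hip and stifle
#' constraints hold exactly because the chain is parameterized in minimal
#' coordinates ([fk_poses()]).
#'
#' @param markers_frame named m x 3 matrix of observed marker positions
#'   (mm); rows with non-finite entries count as invisible.
#' @param model a `multibody_model`.
#' @param weights named per-marker weights (default: model weights).
#' @param init length-12 starting DOF vector.
#' @param max_iter iteration cap (default 200).
#' @return list with `q` (the solution), `poses`, `residual` (weighted RMS
#'   marker distance, mm), `iterations`, `converged`.
#' @export
mko_solve_frame <- function(markers_frame, model, weights = NULL, init,
                            max_iter = 200) {
  if (length(init) != 12 || !all(is.finite(init)))
    stop("mko_solve_frame: init must be 12 finite numbers", call. = FALSE)
  w_all <- if (is.null(weights)) model$weights else weights
  obs <- as.matrix(markers_frame)
  seg_of <- segment_of_marker()
  cand <- intersect(rownames(obs), model$dynamic)
  vis <- cand[apply(is.finite(obs[cand, , drop = FALSE]), 1, all) &
              w_all[cand] > 0]
  segs_seen <- unique(seg_of[vis])
  if (length(vis) < 6 || length(segs_seen) < 3)
    stop("mko_solve_frame: need >= 6 visible markers spanning all three segments",
         call. = FALSE)
  sqw <- sqrt(w_all[vis])
  fn <- mko_residual_fn(model, obs, vis, sqw, seg_of)
  fit <- minpack.lm::nls.lm(par = init, fn = fn,
                            control = minpack.lm::nls.lm.control(
                              ftol = 1e-10, ptol = 1e-12, gtol = 1e-8,
                              maxiter = max_iter))
  q <- as.numeric(fit$par)
  if (any(abs(((q[c(5, 8, 11)] + 90) %% 180) - 90) > 80))
    warning("mko_solve_frame: adduction/abduction within 10 deg of gimbal lock")
  res <- fn(q)
  structure(list(q = q, poses = fk_poses(model, q),
                 residual = sqrt(sum(res^2) / sum(sqw^2)),
                 iterations = fit$niter,
                 converged = fit$info %in% 1:4),
            class = "mko_frame")
}

#' Multibody kinematics optimization tracking
#'
#' Runs [mko_solve_frame()] over a whole trial. The first frame is
#' initialized from the single-body solution of that frame projected onto
#' the chain ([poses_to_dof()]); each subsequent frame warm-starts from
#' the previous solution.
#'
#' @inheritParams so_track
#' @return a `tracking_result` with `method = "mko"`, per-frame `poses`,
#'   `dof` (frames x 12 matrix), `residual`, `iterations` and `converged`
#'   per frame.
#' @export
mko_track <- function(trajectories, model, weights = NULL) {
  w_all <- if (is.null(weights)) model$weights else weights
  n <- trajectories$n_frames
  so1 <- so_track(subset_frames(trajectories, 1L), model, w_all)
  if (!all(so1$valid[1, ]))
    stop("mko_track: single-body initialization failed on the first frame",
         call. = FALSE)
  init <- poses_to_dof(so1$poses[[1]])
  poses <- vector("list", n)
  dof <- matrix(NA_real_, n, 12)
  residual <- rep(NA_real_, n)
  iterations <- integer(n)
  converged <- logical(n)
  valid <- matrix(FALSE, n, 3,
                  dimnames = list(NULL, c("pelvis", "femur", "tibia")))
  for (k in seq_len(n)) {
    sol <- try(mko_solve_frame(frame_markers(trajectories, k), model,
                               w_all, init), silent = TRUE)
    if (inherits(sol, "try-error")) next
    poses[[k]] <- sol$poses
    dof[k, ] <- sol$q
    residual[k] <- sol$residual
    iterations[k] <- sol$iterations
    converged[k] <- sol$converged
    valid[k, ] <- TRUE
    init <- sol$q
  }
  structure(list(method = "mko", poses = poses, valid = valid, dof = dof,
                 residual = residual, iterations = iterations,
                 converged = converged, time = trajectories$time,
                 rate_hz = trajectories$rate_hz),
            class = "tracking_result")
}

#' @export
print.tracking_result <- function(x, ...) {
  n <- length(x$poses)
  ok <- sum(apply(x$valid, 1, all))
  cat(sprintf("<tracking_result> method=%s, %d frames (%d fully valid)\n",
              toupper(x$method), n, ok))
  cat(sprintf("  weighted RMS marker residual: median %.3f mm\n",
              stats::median(x$residual, na.rm = TRUE)))
  invisible(x)
}

subset_frames <- function(traj, idx) {
  marker_trajectories(traj$xyz[idx, , , drop = FALSE], traj$rate_hz,
                      traj$time[idx])
}

#' Local marker displacement with respect to the tracked bone
#'
#' For each dynamic marker, expresses its measured position in its
#' segment's single-body-determined anatomical frame at every valid frame
#' and reports the mean distance from its temporal mean local position.
#' This is the displacement amplitude used to derive marker weights.
#'
#' By default the segment frame for a marker is re-fitted from the
#' segment's *other* markers (leave-one-out): a marker's own artefact
#' then cannot drag the frame along with it, so an injected deformation
#' on one marker is recovered at full amplitude when the rest of the
#' cluster is clean. With `leave_one_out = FALSE` the all-marker
#' single-body frame is used; part of each marker's deformation is then
#' absorbed into the fitted pose and the displacement underestimates the
#' artefact. Either way the metric has a structural blind spot: an
#' artefact moving the whole cluster rigidly leaves local positions
#' unchanged and is invisible here.
#'
#' @param trajectories a `marker_trajectories` (one gait cycle or more).
#' @param so_result the matching [so_track()] result.
#' @param model a `multibody_model`.
#' @param leave_one_out re-fit the segment frame without the probed
#'   marker (default TRUE; falls back to the all-marker frame when fewer
#'   than 3 other markers are visible).
#' @return named numeric vector of displacements (mm) over the dynamic
#'   markers; markers never visible are dropped with a warning.
#' @export
local_marker_displacement <- function(trajectories, so_result, model,
                                      leave_one_out = TRUE) {
  seg_of <- segment_of_marker()
  out <- numeric(0)
  dropped <- character(0)
  for (mk in intersect(model$dynamic, trajectories$markers)) {
    s <- seg_of[[mk]]
    rows <- which(trajectories$visible[, mk] & so_result$valid[, s])
    if (!length(rows)) { dropped <- c(dropped, mk); next }
    tmpl <- model$templates[[s]]
    others <- setdiff(intersect(intersect(rownames(tmpl), model$dynamic),
                                trajectories$markers), mk)
    loc <- t(vapply(rows, function(k) {
      pose <- so_result$poses[[k]][[s]]
      if (leave_one_out) {
        vis <- others[trajectories$visible[k, others]]
        if (length(vis) >= 3) {
          alt <- try(weighted_rigid_fit(
            tmpl[vis, , drop = FALSE],
            t(trajectories$xyz[k, , vis]),
            model$weights[vis]), silent = TRUE)
          if (!inherits(alt, "try-error")) pose <- alt
        }
      }
      rt_apply(rt_inverse(pose), trajectories$xyz[k, , mk])
    }, numeric(3)))
    ctr <- colMeans(loc)
    out[mk] <- mean(sqrt(rowSums(sweep(loc, 2, ctr)^2)))
  }
  if (length(dropped))
    warning("markers never visible, excluded: ",
            paste(dropped, collapse = ", "))
  out
}

#' Marker weights from local displacement
#'
#' Weights each marker by the reciprocal of its local displacement,
#' floored to avoid a near-rigid marker dominating, then normalized so the
#' mean weight equals 1 (making weighted and unweighted costs comparable).
#'
#' @param displacements named non-negative displacements (mm), e.g. from
#'   [local_marker_displacement()].
#' @param floor displacement floor (mm, default 0.5).
#' @return named weights with mean 1.
#' @export
weights_from_displacement <- function(displacements, floor = 0.5) {
  if (!length(displacements))
    stop("weights_from_displacement: empty displacement map", call. = FALSE)
  if (any(!is.finite(displacements)) || any(displacements < 0))
    stop("weights_from_displacement: displacements must be finite and >= 0",
         call. = FALSE)
  w <- 1 / pmax(displacements, floor)
  w / mean(w)
}
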