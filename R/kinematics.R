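#' Joint angles from tracked segment poses
#'
#' Hip angles are the Cardan z-x-y decomposition of the pelvis-to-femur
#' relative rotation, stifle angles of the femur-to-tibia relative
#' rotation: flexion/extension, adduction/abduction, internal/external
#' rotation, in that order. Frames where either segment is invalid yield
#' `NA`.
#'
#' @param tracking a `tracking_result` from [so_track()] or [mko_track()].
#' @return matrix (frames x 6, deg) with columns `hip_fe`, `hip_aa`,
#'   `hip_ie`, `stifle_fe`, `stifle_aa`, `stifle_ie`; attribute `time`.
#' @export
compute_joint_angles <- function(tracking) {
  n <- length(tracking$poses)
  out <- matrix(NA_real_, n, 6,
                dimnames = list(NULL, c("hip_fe", "hip_aa", "hip_ie",
                                        "stifle_fe", "stifle_aa", "stifle_ie")))
  for (k in seq_len(n)) {
    pk <- tracking$poses[[k]]
    if (is.null(pk)) next
    if (tracking$valid[k, "pelvis"] && tracking$valid[k, "femur"]) {
      hip <- tryCatch(rotation_to_cardan_zxy(t(pk$pelvis$R) %*% pk$femur$R),
                      error = function(e)
                        stop("gimbal lock at frame ", k, ": ",
                             conditionMessage(e), call. = FALSE))
      out[k, 1:3] <- hip
    }
    if (tracking$valid[k, "femur"] && tracking$valid[k, "tibia"]) {
      out[k, 4:6] <- tryCatch(
        rotation_to_cardan_zxy(t(pk$femur$R) %*% pk$tibia$R),
        error = function(e)
          stop("gimbal lock at frame ", k, ": ",
               conditionMessage(e), call. = FALSE))
    }
  }
  attr(out, "time") <- tracking$time
  out
}

#' Detect paw contacts from the foot marker
#'
#' On a treadmill the foot marker reaches its cranial-most excursion at
#' paw contact, so contacts are the downward zero-crossings of the
#' low-pass-filtered fore-aft velocity of the foot marker. Filtering uses
#' a zero-phase (forward-backward) 2nd-order Butterworth low-pass, 6 Hz
#' default cutoff.
#'
#' @param foot_xyz n x 3 matrix of foot marker positions (mm).
#' @param rate_hz sampling rate (Hz).
#' @param direction unit vector of the direction of travel (default +x).
#' @param cutoff_hz low-pass cutoff (Hz).
#' @return strictly increasing integer frame indices of the detected
#'   contacts.
#' @export
detect_paw_contacts <- function(foot_xyz, rate_hz, direction = c(1, 0, 0),
                                cutoff_hz = 6) {
  P <- as.matrix(foot_xyz)
  if (nrow(P) < 5) stop("detect_paw_contacts: too few frames", call. = FALSE)
  d <- unit(as.numeric(direction))
  x <- as.numeric(P %*% d)
  if (stats::sd(x) < 1e-6)
    stop("detect_paw_contacts: no events (stationary foot marker)", call. = FALSE)
  wn <- min(cutoff_hz / (rate_hz / 2), 0.99)
  bf <- signal::butter(2, wn)
  xf <- as.numeric(signal::filtfilt(bf, x))
  v <- c(diff(xf)[1], diff(xf, lag = 2) / 2, diff(xf)[length(xf) - 1]) * rate_hz
  idx <- which(v[-length(v)] >= 0 & v[-1] < 0)
  # sub-sample refinement: crossing closer to whichever side has |v| smaller
  idx <- ifelse(abs(v[idx]) <= abs(v[idx + 1]), idx, idx + 1L)
  # enforce a refractory period of 0.2 s between contacts
  if (length(idx) > 1) {
    keep <- c(TRUE, diff(idx) > 0.2 * rate_hz)
    idx <- idx[keep]
  }
  if (!length(idx))
    stop("detect_paw_contacts: no events found", call. = FALSE)
  as.integer(idx)
}

#' Normalize a time series to the gait cycle
#'
#' Linearly interpolates each column of a series onto 101 evenly spaced
#' points spanning 0-100% of each gait cycle (between successive
#' contacts). Cycles shorter than 10 frames are rejected with a warning.
#'
#' @param series numeric matrix (frames x components) or vector.
#' @param contacts increasing frame indices of paw contacts (>= 2).
#' @param n_points samples per cycle (default 101, i.e. 0-100% inclusive).
#' @return list of `n_points` x components matrices, one per retained
#'   cycle.
#' @export
normalize_to_gait_cycle <- function(series, contacts, n_points = 101) {
  S <- as.matrix(series)
  if (length(contacts) < 2)
    stop("normalize_to_gait_cycle: need at least 2 contacts", call. = FALSE)
  contacts <- as.integer(contacts)
  out <- list()
  for (c_i in seq_len(length(contacts) - 1)) {
    i0 <- contacts[c_i]; i1 <- contacts[c_i + 1]
    if (i1 - i0 < 10) {
      warning(sprintf("cycle %d shorter than 10 frames; rejected", c_i))
      next
    }
    if (i0 < 1 || i1 > nrow(S))
      stop("normalize_to_gait_cycle: contact outside the series", call. = FALSE)
    xq <- seq(i0, i1, length.out = n_points)
    cyc <- apply(S[, , drop = FALSE], 2, function(col)
      stats::approx(seq_len(nrow(S)), col, xout = xq)$y)
    out[[length(out) + 1]] <- cyc
  }
  out
}

#' Waveform agreement statistics
#'
#' Compares an estimated waveform against a reference: Bland-Altman bias
#' (mean difference) and CI (half-width of the 95% limits of agreement,
#' 1.96 x SD of the differences; set `ci_type = "bias"` for the 95%
#' confidence half-width of the bias itself), the coefficient of
#' determination from ordinary regression of test on reference, and the
#' root-mean-square difference.
#'
#' @param test,reference equal-length numeric vectors (deg). Matrices are
#'   flattened, pooling cycles.
#' @param ci_type `"loa"` (default, limits-of-agreement half-width) or
#'   `"bias"`.
#' @return list of class `agreement_report`: `bias`, `ci`, `r_squared`,
#'   `rmsd`, `n`.
#' @export
agreement_stats <- function(test, reference, ci_type = c("loa", "bias")) {
  ci_type <- match.arg(ci_type)
  x <- as.numeric(test); y <- as.numeric(reference)
  if (length(x) != length(y))
    stop("agreement_stats: waveform lengths differ", call. = FALSE)
  d <- x - y
  n <- length(d)
  bias <- mean(d)
  sdd <- stats::sd(d)
  ci <- if (ci_type == "loa") 1.96 * sdd else 1.96 * sdd / sqrt(n)
  r2 <- if (stats::sd(x) < 1e-12 || stats::sd(y) < 1e-12) 1
        else stats::cor(x, y)^2
  structure(list(bias = bias, ci = if (is.na(ci)) 0 else ci,
                 r_squared = r2, rmsd = sqrt(mean(d^2)), n = n),
            class = "agreement_report")
}

#' @export
print.agreement_report <- function(x, ...) {
  cat(sprintf("<agreement_report> n=%d  bias %.2f deg  CI %.2f deg  R^2 %.3f  RMSD %.2f deg\n",
              x$n, x$bias, x$ci, x$r_squared, x$rmsd))
  invisible(x)
}

#' Per-cycle RMSD averaged per subject
#'
#' Computes the RMSD between matched normalized cycles and averages over
#' the subject's cycles (the subject-level summary used in the
#' between-method comparisons; bias/CI/R-squared are computed on pooled
#' cycles instead).
#'
#' @param test_cycles,reference_cycles lists of equal-shaped cycle
#'   matrices (e.g. from [normalize_to_gait_cycle()]).
#' @return named numeric of per-component RMSD (deg), averaged over
#'   cycles.
#' @export
cycle_rmsd <- function(test_cycles, reference_cycles) {
  if (length(test_cycles) != length(reference_cycles))
    stop("cycle_rmsd: cycle counts differ", call. = FALSE)
  per_cycle <- vapply(seq_along(test_cycles), function(i) {
    d <- as.matrix(test_cycles[[i]]) - as.matrix(reference_cycles[[i]])
    sqrt(colMeans(d^2))
  }, numeric(ncol(as.matrix(test_cycles[[1]]))))
  if (is.null(dim(per_cycle))) per_cycle <- matrix(per_cycle, 1)
  rowMeans(per_cycle)
}

#' Paired comparison with a normality gate
#'
#' Tests paired per-subject values: the Shapiro-Wilk test on the
#' differences (alpha = 0.05) selects between a paired t-test (normal)
#' and the Wilcoxon signed-rank test (otherwise). The gate is part of the
#' procedure, never a user choice after seeing results. If every
#' difference is zero the comparison is degenerate (p = 1, flagged).
#'
#' @param a,b equal-length (>= 3) paired numeric vectors.
#' @param alpha significance level (default 0.05).
#' @return list of class `paired_comparison`: `normality_p`, `test`
#'   (`"paired-t"`, `"wilcoxon"` or `"degenerate"`), `statistic`,
#'   `p_value`, `significant`, `mean_difference`.
#' @export
paired_compare <- function(a, b, alpha = 0.05) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) != length(b) || length(a) < 3)
    stop("paired_compare: need equal-length paired samples, n >= 3", call. = FALSE)
  d <- a - b
  if (all(d == 0))
    return(structure(list(normality_p = NA_real_, test = "degenerate",
                          statistic = NA_real_, p_value = 1,
                          significant = FALSE, mean_difference = 0),
                     class = "paired_comparison"))
  np <- stats::shapiro.test(d)$p.value
  if (np >= alpha) {
    ht <- stats::t.test(a, b, paired = TRUE)
    test <- "paired-t"
  } else {
    ht <- stats::wilcox.test(a, b, paired = TRUE, exact = FALSE)
    test <- "wilcoxon"
  }
  structure(list(normality_p = np, test = test,
                 statistic = unname(ht$statistic), p_value = ht$p.value,
                 significant = ht$p.value < alpha, mean_difference = mean(d)),
            class = "paired_comparison")
}

#' @export
print.paired_comparison <- function(x, ...) {
  cat(sprintf("<paired_comparison> %s: statistic %.3f, p %.4g (%ssignificant at 0.05), mean diff %.3f\n",
              x$test, x$statistic %||% NA, x$p_value,
              if (isTRUE(x$significant)) "" else "not ", x$mean_difference))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a) || length(a) == 0) b else a
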