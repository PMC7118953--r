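#' Read a TRC marker trajectory file
#'
#' TRC is the tab-separated interchange dialect used by this package:
#' header rows 1-5 (file type, field names, field values, marker names,
#' XYZ column labels) followed by one row per frame (frame number, time,
#' XYZ per marker). Coordinates must be in mm; files in m or cm are
#' converted on load with a warning. Blank coordinate cells mark
#' invisible samples.
#'
#' @param path TRC file path.
#' @return a `marker_trajectories`.
#' @export
read_trc <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 6)
    stop("malformed TRC header (fewer than 6 lines): ", path, call. = FALSE)
  hdr_names <- strsplit(lines[2], "\t")[[1]]
  hdr_vals <- strsplit(lines[3], "\t")[[1]]
  hd <- stats::setNames(as.list(hdr_vals), hdr_names[seq_along(hdr_vals)])
  rate <- suppressWarnings(as.numeric(hd[["DataRate"]]))
  n_markers <- suppressWarnings(as.integer(hd[["NumMarkers"]]))
  units <- hd[["Units"]]
  if (is.null(rate) || is.na(rate) || is.na(n_markers))
    stop("malformed TRC header at line 3: ", path, call. = FALSE)
  scale <- switch(units, mm = 1, m = 1000, cm = 10,
                  stop("TRC units not recognized (line 3): ", units, call. = FALSE))
  if (scale != 1)
    warning(sprintf("TRC units '%s' converted to mm", units))
  mk_row <- strsplit(lines[4], "\t")[[1]]
  markers <- mk_row[nzchar(mk_row)][-(1:2)]
  if (length(markers) != n_markers)
    stop(sprintf("TRC header inconsistency at line 4: %d marker names, NumMarkers=%d",
                 length(markers), n_markers), call. = FALSE)
  data_lines <- lines[-(1:5)]
  data_lines <- data_lines[nzchar(trimws(data_lines))]
  n <- length(data_lines)
  xyz <- array(NA_real_, c(n, 3, n_markers),
               dimnames = list(NULL, c("x", "y", "z"), markers))
  time <- numeric(n)
  for (k in seq_len(n)) {
    cells <- strsplit(data_lines[k], "\t")[[1]]
    if (length(cells) < 2)
      stop("malformed TRC data at line ", k + 5, call. = FALSE)
    time[k] <- as.numeric(cells[2])
    vals <- suppressWarnings(as.numeric(cells[-(1:2)]))
    length(vals) <- 3 * n_markers
    xyz[k, , ] <- matrix(vals, 3) * scale
  }
  marker_trajectories(xyz, rate, time)
}

fmt_num <- function(x, digits = 6) {
  ifelse(is.finite(x), sprintf(paste0("%.", digits, "f"), x), "")
}

#' Write a TRC marker trajectory file
#'
#' Deterministic writer: fixed column order and fixed 6-decimal float
#' formatting, so identical inputs produce byte-identical files and a
#' write/read round trip preserves coordinates to 1e-6 mm.
#'
#' @param trajectories a `marker_trajectories`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_trc <- function(trajectories, path) {
  tr <- trajectories
  m <- length(tr$markers)
  hdr <- c(
    paste0("PathFileType\t4\t(X/Y/Z)\t", basename(path)),
    "DataRate\tCameraRate\tNumFrames\tNumMarkers\tUnits\tOrigDataRate\tOrigDataStartFrame\tOrigNumFrames",
    sprintf("%g\t%g\t%d\t%d\tmm\t%g\t1\t%d", tr$rate_hz, tr$rate_hz,
            tr$n_frames, m, tr$rate_hz, tr$n_frames),
    paste(c("Frame#", "Time",
            as.vector(rbind(tr$markers, "", ""))), collapse = "\t"),
    paste(c("", "", paste0(rep(c("X", "Y", "Z"), m),
                           rep(seq_len(m), each = 3))), collapse = "\t"))
  rows <- vapply(seq_len(tr$n_frames), function(k) {
    paste(c(k, sprintf("%.6f", tr$time[k]),
            fmt_num(as.numeric(tr$xyz[k, , ]))), collapse = "\t")
  }, character(1))
  writeLines(c(hdr, rows), path)
  invisible(path)
}

#' Read marker trajectories from wide CSV
#'
#' Wide layout: columns `frame`, `time`, then `<marker>_x`, `<marker>_y`,
#' `<marker>_z` per marker. Empty cells mark invisible samples. Semantics
#' are identical to [read_trc()].
#'
#' @param path CSV path.
#' @param rate_hz sampling rate; if `NULL`, inferred from the time column.
#' @return a `marker_trajectories`.
#' @export
read_markers_csv <- function(path, rate_hz = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, check.names = FALSE)
  if (nrow(df) == 0) stop("empty marker file: ", path, call. = FALSE)
  if (!all(c("frame", "time") %in% names(df)))
    stop("missing column(s): ",
         paste(setdiff(c("frame", "time"), names(df)), collapse = ", "),
         call. = FALSE)
  if (anyDuplicated(df$frame))
    stop("duplicate frame rows in ", path, call. = FALSE)
  coord_cols <- grep("_[xyz]$", names(df), value = TRUE)
  markers <- unique(sub("_[xyz]$", "", coord_cols))
  for (mk in markers) {
    miss <- setdiff(paste0(mk, "_", c("x", "y", "z")), names(df))
    if (length(miss))
      stop("missing column(s): ", paste(miss, collapse = ", "), call. = FALSE)
  }
  n <- nrow(df)
  xyz <- array(NA_real_, c(n, 3, length(markers)),
               dimnames = list(NULL, c("x", "y", "z"), markers))
  for (i in seq_along(markers))
    xyz[, , i] <- as.matrix(df[paste0(markers[i], "_", c("x", "y", "z"))])
  if (is.null(rate_hz))
    rate_hz <- 1 / stats::median(diff(df$time))
  marker_trajectories(xyz, rate_hz, df$time)
}

#' Read a point cloud from CSV or ASCII PLY
#'
#' CSV files need an `x,y,z` header; PLY files must be ASCII with vertex
#' elements (only the vertex coordinates are read).
#'
#' @param path file path (`.csv` or `.ply`).
#' @return n x 3 numeric matrix (mm).
#' @export
read_point_cloud <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (grepl("\\.ply$", path, ignore.case = TRUE)) {
    lines <- readLines(path, warn = FALSE)
    if (!identical(tolower(trimws(lines[1])), "ply"))
      stop("not a PLY file: ", path, call. = FALSE)
    if (!any(grepl("^format\\s+ascii", lines)))
      stop("only ASCII PLY is supported: ", path, call. = FALSE)
    nv <- as.integer(sub("^element\\s+vertex\\s+", "",
                         grep("^element\\s+vertex\\s+", lines, value = TRUE)[1]))
    end <- which(trimws(lines) == "end_header")[1]
    if (is.na(nv) || is.na(end))
      stop("malformed PLY header: ", path, call. = FALSE)
    vals <- do.call(rbind, lapply(lines[end + seq_len(nv)], function(l)
      as.numeric(strsplit(trimws(l), "\\s+")[[1]][1:3])))
    colnames(vals) <- c("x", "y", "z")
    return(vals)
  }
  df <- utils::read.csv(path)
  if (!all(c("x", "y", "z") %in% names(df)))
    stop("point cloud CSV needs x,y,z columns: ", path, call. = FALSE)
  as.matrix(df[c("x", "y", "z")])
}

num12 <- function(x) as.numeric(formatC(x, digits = 12, format = "g"))

rt_to_mat4 <- function(tf) {
  m <- rbind(cbind(tf$R, tf$t), c(0, 0, 0, 1))
  as.numeric(t(m))  # row-major
}

mat4_to_rt <- function(v) {
  m <- matrix(as.numeric(v), 4, 4, byrow = TRUE)
  rigid_transform(m[1:3, 1:3], m[1:3, 4])
}

#' Serialize a multibody model to YAML
#'
#' Frames are stored as row-major 4x4 matrices, templates and joint
#' centres as mm triples. Numbers are written with 12 significant digits,
#' making the file byte-stable across repeated writes and exact to
#' round-trip precision.
#'
#' @param model a `multibody_model`.
#' @param path output path (`.yaml`/`.yml` or `.json`).
#' @return `path`, invisibly.
#' @export
write_model <- function(model, path) {
  obj <- list(
    format = "mkogait-model-1",
    frames = lapply(model$frames, function(f) num12(rt_to_mat4(f))),
    templates = lapply(model$templates, function(tm) {
      out <- lapply(seq_len(nrow(tm)), function(i) num12(tm[i, ]))
      names(out) <- rownames(tm)
      out
    }),
    centres = lapply(unclass(model$centres), num12),
    weights = as.list(stats::setNames(num12(model$weights),
                                      names(model$weights))),
    dynamic = as.list(model$dynamic))
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  } else {
    yaml::write_yaml(obj, path, precision = 12)
  }
  invisible(path)
}

#' Read a multibody model written by [write_model()]
#'
#' @param path model file path (`.yaml`/`.yml` or `.json`).
#' @return a `multibody_model`.
#' @export
read_model <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  obj <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = TRUE)
  else yaml::read_yaml(path)
  if (!identical(obj$format, "mkogait-model-1"))
    stop("not an mkogait model file: ", path, call. = FALSE)
  frames <- lapply(obj$frames, mat4_to_rt)
  templates <- lapply(obj$templates, function(tm) {
    m <- do.call(rbind, lapply(tm, as.numeric))
    rownames(m) <- names(tm)
    colnames(m) <- c("x", "y", "z")
    m
  })
  centres <- structure(lapply(obj$centres, as.numeric), class = "joint_centres")
  weights <- unlist(obj$weights)
  assemble_model(frames, templates, centres, weights,
                 dynamic = unlist(obj$dynamic))
}

#' Write/read tracked poses as CSV
#'
#' One row per frame: frame index, time, each segment's pose flattened as
#' a row-major 4x4 matrix, the weighted RMS residual and a convergence
#' flag. Invalid segment-frames are written as empty cells.
#'
#' @param tracking a `tracking_result`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_poses_csv <- function(tracking, path) {
  segs <- c("pelvis", "femur", "tibia")
  cols <- unlist(lapply(segs, function(s) paste0(s, "_m", 1:16)))
  n <- length(tracking$poses)
  rows <- character(n)
  for (k in seq_len(n)) {
    vals <- unlist(lapply(segs, function(s) {
      if (tracking$valid[k, s]) fmt_num(rt_to_mat4(tracking$poses[[k]][[s]]), 9)
      else rep("", 16)
    }))
    rows[k] <- paste(c(k, sprintf("%.6f", tracking$time[k]), vals,
                       fmt_num(tracking$residual[k], 6),
                       as.integer(all(tracking$valid[k, ]))), collapse = ",")
  }
  writeLines(c(paste(c("frame", "time", cols, "residual", "valid"),
                     collapse = ","), rows), path)
  invisible(path)
}

#' @rdname write_poses_csv
#' @param method tracking method label to attach (`"so"` or `"mko"`).
#' @export
read_poses_csv <- function(path, method = "unknown") {
  df <- utils::read.csv(path, check.names = FALSE)
  segs <- c("pelvis", "femur", "tibia")
  n <- nrow(df)
  poses <- vector("list", n)
  valid <- matrix(FALSE, n, 3, dimnames = list(NULL, segs))
  for (k in seq_len(n)) {
    pk <- list(pelvis = NULL, femur = NULL, tibia = NULL)
    for (s in segs) {
      v <- as.numeric(df[k, paste0(s, "_m", 1:16)])
      if (all(is.finite(v))) {
        pk[[s]] <- mat4_to_rt(v)
        valid[k, s] <- TRUE
      }
    }
    poses[[k]] <- pk
  }
  structure(list(method = method, poses = poses, valid = valid,
                 residual = df$residual, time = df$time,
                 rate_hz = 1 / stats::median(diff(df$time))),
            class = "tracking_result")
}

#' Write gait-cycle-normalized angle waveforms as CSV
#'
#' One row per percent gait cycle (0-100), columns `pct_cycle`, then
#' `cycle<i>_<component>` for each cycle and angle component, 6 decimals.
#'
#' @param cycles list of 101 x 6 matrices from [normalize_to_gait_cycle()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_angles_csv <- function(cycles, path) {
  comp <- colnames(cycles[[1]])
  if (is.null(comp)) comp <- paste0("c", seq_len(ncol(cycles[[1]])))
  hdr <- c("pct_cycle", unlist(lapply(seq_along(cycles), function(i)
    paste0("cycle", i, "_", comp))))
  np <- nrow(cycles[[1]])
  pct <- seq(0, 100, length.out = np)
  body <- vapply(seq_len(np), function(r) {
    paste(c(sprintf("%.1f", pct[r]),
            unlist(lapply(cycles, function(cy) fmt_num(cy[r, ], 6)))),
          collapse = ",")
  }, character(1))
  writeLines(c(paste(hdr, collapse = ","), body), path)
  invisible(path)
}

#' @rdname write_angles_csv
#' @export
read_angles_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  cyc_cols <- grep("^cycle\\d+_", names(df), value = TRUE)
  ids <- unique(sub("_.*$", "", cyc_cols))
  lapply(ids, function(id) {
    cols <- grep(paste0("^", id, "_"), names(df), value = TRUE)
    m <- as.matrix(df[cols])
    colnames(m) <- sub(paste0(id, "_"), "", cols)
    m
  })
}
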