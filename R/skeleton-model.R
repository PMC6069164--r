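# Skeleton-stream domain types and on-disk formats.
#
# A stream is stored wide: one row per frame with columns
#   frame, t, floor_A..floor_D, <joint>_{x,y,z,state}
# over the 20-joint vocabulary.  Coordinates are meters in sensor space,
# x right / y up / z depth (away from the sensor).

#' Joint vocabulary
#'
#' The 20 named joints of a v1-style depth-sensor skeleton, in canonical
#' order.  Side-specific joints carry `_l` / `_r` suffixes.
#'
#' @return character vector of 20 joint names.
#' @export
fs_joints <- function() {
  c("head", "shoulder_center", "torso", "hip_center",
    "shoulder_l", "shoulder_r", "elbow_l", "elbow_r",
    "wrist_l", "wrist_r", "hand_l", "hand_r",
    "hip_l", "hip_r", "knee_l", "knee_r",
    "ankle_l", "ankle_r", "foot_l", "foot_r")
}

tracking_states <- c("tracked", "inferred", "not_tracked")

joint_cols <- function() {
  as.vector(t(outer(fs_joints(), c("x", "y", "z", "state"),
                    function(j, s) paste(j, s, sep = "_"))))
}

stream_cols <- function() {
  c("frame", "t", "floor_A", "floor_B", "floor_C", "floor_D", joint_cols())
}

#' Construct a joint position
#'
#' @param x,y,z coordinates in meters (sensor space: x right, y up, z depth).
#' @param state tracking state, one of `"tracked"`, `"inferred"`,
#'   `"not_tracked"`.
#' @return a `joint_position` list.
#' @export
joint_position <- function(x, y, z, state = "tracked") {
  state <- match.arg(state, tracking_states)
  if (state != "not_tracked") {
    if (!all(is.finite(c(x, y, z)))) {
      stop("coordinates must be finite for a tracked/inferred joint",
           call. = FALSE)
    }
    if (z < 0) {
      stop("z must be >= 0 for a tracked joint (subject in front of sensor)",
           call. = FALSE)
    }
  }
  structure(list(x = x, y = y, z = z, state = state),
            class = "joint_position")
}

#' Construct a floor plane
#'
#' The floor-clipping vector `(A, B, C, D)` reported by the sensor: the plane
#' `Ax + By + Cz + D = 0` in sensor space.  `D` is the height of the camera
#' above the floor in meters.
#'
#' @param A,B,C plane normal components (unitless).
#' @param D camera height above the floor, meters (non-negative).
#' @return a `floor_plane` numeric vector.
#' @export
floor_plane <- function(A, B, C, D) {
  v <- c(A = A, B = B, C = C, D = D)
  if (!all(is.finite(v))) stop("floor plane must be finite", call. = FALSE)
  if (A^2 + B^2 + C^2 <= 0) {
    stop("degenerate floor plane: A^2 + B^2 + C^2 must be > 0", call. = FALSE)
  }
  if (D < 0) stop("D (camera height) must be >= 0", call. = FALSE)
  structure(v, class = "floor_plane")
}

#' Construct a skeleton stream
#'
#' Validates and wraps a wide per-frame data frame (see [read_skeleton_csv()]
#' for the column layout) together with stream metadata.
#'
#' @param frames data frame with columns `frame`, `t`, `floor_A..floor_D` and
#'   `<joint>_{x,y,z,state}` for the twenty joints of [fs_joints()].
#' @param fps nominal frame rate, frames/s.
#' @param camera_height camera height above the floor, meters (defaults to the
#'   median `floor_D`).
#' @param source free-text provenance tag.
#' @param validate run invariant checks (strictly increasing `frame` and `t`).
#' @return a `skeleton_stream` object: `list(frames, metadata)` with the frame
#'   data frame and a metadata list.  Frames whose spacing deviates from
#'   `1/fps` by more than 20% are flagged in `attr(, "gaps")`.
#' @export
skeleton_stream <- function(frames, fps = 30, camera_height = NULL,
                            source = "unknown", validate = TRUE) {
  stopifnot(is.data.frame(frames))
  missing_cols <- setdiff(stream_cols(), names(frames))
  if (length(missing_cols) > 0L) {
    stop("missing skeleton column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  frames <- frames[, stream_cols()]
  if (validate && nrow(frames) > 1L) {
    if (any(diff(frames$t) <= 0)) {
      stop("timestamps must be strictly increasing along a stream",
           call. = FALSE)
    }
    if (any(diff(frames$frame) <= 0)) {
      stop("frame indices must be strictly increasing", call. = FALSE)
    }
  }
  if (is.null(camera_height)) {
    camera_height <- stats::median(frames$floor_D)
  }
  gaps <- integer(0)
  if (nrow(frames) > 1L) {
    dt <- diff(frames$t)
    gaps <- which(abs(dt - 1 / fps) > 0.2 / fps)
  }
  out <- structure(
    list(frames = frames,
         metadata = list(source = source, fps = fps,
                         camera_height = camera_height)),
    class = "skeleton_stream")
  attr(out, "gaps") <- gaps
  out
}

#' Number of frames in a stream
#' @param stream a `skeleton_stream`.
#' @return integer frame count.
#' @export
n_frames <- function(stream) nrow(stream$frames)

#' Extract one frame as a structured snapshot
#'
#' @param stream a `skeleton_stream`.
#' @param i frame row index (1-based).
#' @return a `skeleton_frame` list: `frame_index`, `t`, `floor`
#'   ([floor_plane()]) and `joints` (named list of [joint_position()]).
#' @export
get_frame <- function(stream, i) {
  row <- stream$frames[i, , drop = FALSE]
  if (nrow(row) != 1L) stop("frame index out of range", call. = FALSE)
  joints <- lapply(fs_joints(), function(j) {
    st <- as.character(row[[paste0(j, "_state")]])
    x <- row[[paste0(j, "_x")]]
    if (is.na(st) || !(st %in% tracking_states)) st <- "not_tracked"
    if (st != "not_tracked" &&
        (is.na(x) || is.na(row[[paste0(j, "_y")]]) ||
         is.na(row[[paste0(j, "_z")]]))) {
      st <- "not_tracked"
    }
    structure(list(x = row[[paste0(j, "_x")]], y = row[[paste0(j, "_y")]],
                   z = row[[paste0(j, "_z")]], state = st),
              class = "joint_position")
  })
  names(joints) <- fs_joints()
  structure(
    list(frame_index = row$frame, t = row$t,
         floor = floor_plane(row$floor_A, row$floor_B, row$floor_C,
                             row$floor_D),
         joints = joints),
    class = "skeleton_frame")
}

#' @export
print.skeleton_stream <- function(x, ...) {
  cat(sprintf("<skeleton_stream> %d frames, %.2f s @ %g fps (%s)\n",
              n_frames(x),
              if (n_frames(x) > 1) diff(range(x$frames$t)) else 0,
              x$metadata$fps, x$metadata$source))
  invisible(x)
}

csv_header_comment <- paste(
  "# skeleton stream: sensor-space meters, x right / y up / z depth;",
  "one row per frame")

#' Write a skeleton stream to CSV
#'
#' One row per frame; numeric values at 6 decimal places; a leading `#`
#' comment line declares the coordinate convention.  Round-trips through
#' [read_skeleton_csv()] at the declared precision.
#'
#' @param stream a non-empty `skeleton_stream`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_skeleton_csv <- function(stream, path) {
  stopifnot(inherits(stream, "skeleton_stream"))
  if (n_frames(stream) == 0L) stop("cannot write an empty stream",
                                   call. = FALSE)
  df <- stream$frames
  num <- vapply(df, is.numeric, logical(1))
  num["frame"] <- FALSE
  df[num] <- lapply(df[num], function(v) sprintf("%.6f", v))
  con <- tryCatch(file(path, "w"), error = function(e) {
    stop("cannot open for writing: ", path, call. = FALSE)
  })
  on.exit(close(con))
  writeLines(csv_header_comment, con)
  utils::write.table(df, con, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a skeleton stream from CSV
#'
#' Expects the layout written by [write_skeleton_csv()]: columns `frame`,
#' `t`, `floor_A..floor_D` and `<joint>_{x,y,z,state}`.  Joints with
#' unparseable or blank coordinate cells are loaded with tracking state
#' `not_tracked`; missing mandatory columns and non-monotone timestamps are
#' errors.
#'
#' @param path input file path.
#' @param fps nominal frame rate recorded in the stream metadata.
#' @return a `skeleton_stream`.
#' @export
read_skeleton_csv <- function(path, fps = 30) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  missing_cols <- setdiff(stream_cols(), names(df))
  if (length(missing_cols) > 0L) {
    stop("missing skeleton column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(df) == 0L) stop("empty skeleton file: ", path, call. = FALSE)
  numcols <- setdiff(stream_cols(), paste0(fs_joints(), "_state"))
  for (cc in numcols) df[[cc]] <- suppressWarnings(as.numeric(df[[cc]]))
  if (anyNA(df$t) || anyNA(df$frame)) {
    stop("non-numeric frame/t values", call. = FALSE)
  }
  # degenerate-cell rule: NA coordinate => joint not tracked in that frame
  for (j in fs_joints()) {
    bad <- is.na(df[[paste0(j, "_x")]]) | is.na(df[[paste0(j, "_y")]]) |
      is.na(df[[paste0(j, "_z")]])
    df[[paste0(j, "_state")]][bad] <- "not_tracked"
  }
  skeleton_stream(df, fps = fps, source = path)
}

#' Write / read a skeleton stream as JSON lines
#'
#' One JSON object per frame with the same field names as the CSV layout.
#'
#' @param stream a non-empty `skeleton_stream`.
#' @param path file path.
#' @return `path` (writer) or a `skeleton_stream` (reader).
#' @export
write_skeleton_jsonl <- function(stream, path) {
  stopifnot(inherits(stream, "skeleton_stream"))
  if (n_frames(stream) == 0L) stop("cannot write an empty stream",
                                   call. = FALSE)
  lines <- vapply(seq_len(n_frames(stream)), function(i) {
    jsonlite::toJSON(as.list(stream$frames[i, ]), auto_unbox = TRUE,
                     digits = 6)
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_skeleton_jsonl
#' @param fps nominal frame rate for the reader.
#' @export
read_skeleton_jsonl <- function(path, fps = 30) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) stop("empty skeleton file: ", path, call. = FALSE)
  rows <- lapply(lines, function(l) {
    as.data.frame(jsonlite::fromJSON(l), stringsAsFactors = FALSE)
  })
  skeleton_stream(do.call(rbind, rows), fps = fps, source = path)
}

#' Read an accelerometer magnitude series
#'
#' Two-column CSV `t, a_mag` (URFD-style export).  Units must be declared:
#' either already SI (`m/s^2`) or g-units, converted with the supplied
#' standard gravity.
#'
#' @param path input CSV path.
#' @param unit `"ms2"` for SI input or `"g"` for g-units.
#' @param g standard gravity used for the g-unit conversion, m/s^2.
#' @return an `acceleration_series` data frame with columns `t` (seconds,
#'   non-decreasing) and `a_mag` (m/s^2).
#' @export
read_accelerometer_csv <- function(path, unit = c("ms2", "g"), g = 9.81) {
  unit <- match.arg(unit)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  if (nrow(df) == 0L) stop("empty accelerometer file: ", path, call. = FALSE)
  if (!all(c("t", "a_mag") %in% names(df))) {
    stop("accelerometer CSV must have columns t, a_mag", call. = FALSE)
  }
  for (cc in c("t", "a_mag")) {
    v <- suppressWarnings(as.numeric(df[[cc]]))
    if (anyNA(v)) {
      stop(sprintf("non-numeric value in column '%s' at row %d", cc,
                   which(is.na(v))[1L]), call. = FALSE)
    }
    df[[cc]] <- v
  }
  if (any(diff(df$t) < 0)) {
    stop("accelerometer timestamps must be non-decreasing", call. = FALSE)
  }
  if (unit == "g") df$a_mag <- df$a_mag * g
  structure(df[, c("t", "a_mag")], class = c("acceleration_series",
                                             "data.frame"))
}

#' Reconstruct a head-height series from accelerometer magnitudes
#'
#' Benchmark-emulation heuristic for replaying accelerometer-only recordings:
#' the initial height comes from a depth frame and the subsequent height
#' change pattern is derived from the acceleration magnitudes.  Two modes:
#' \describe{
#'   \item{`"variation"` (default)}{cumulative subtraction of the deviation
#'     from gravity, `h[i] = h[i-1] - |a[i] - g| * dt * scale`; any deviation
#'     lowers the height, so the series is monotone non-increasing and equals
#'     the initial height for a gravity-only series.}
#'   \item{`"integrate"`}{single integration of `(a - g)` into a vertical
#'     velocity that displaces the height.}
#' }
#' Both are heuristics, not physical models; heights are clipped at 0.
#'
#' @param initial_height starting height, meters (> 0).
#' @param series an `acceleration_series` of length >= 2.
#' @param mode `"variation"` or `"integrate"`.
#' @param g standard gravity, m/s^2.
#' @param scale unitless gain applied in `"variation"` mode.
#' @return numeric height series, same length as `series`, first element
#'   equal to `initial_height`.
#' @export
height_series_from_acceleration <- function(initial_height, series,
                                            mode = c("variation", "integrate"),
                                            g = 9.81, scale = 1) {
  mode <- match.arg(mode)
  if (!is.numeric(initial_height) || initial_height <= 0) {
    stop("initial_height must be > 0", call. = FALSE)
  }
  stopifnot(is.data.frame(series), nrow(series) >= 2L)
  n <- nrow(series)
  h <- numeric(n)
  h[1L] <- initial_height
  dt <- diff(series$t)
  if (mode == "variation") {
    for (i in 2:n) {
      h[i] <- max(0, h[i - 1L] - abs(series$a_mag[i] - g) * dt[i - 1L] * scale)
    }
  } else {
    v <- 0
    for (i in 2:n) {
      v <- v + (series$a_mag[i] - g) * dt[i - 1L]
      h[i] <- max(0, h[i - 1L] + v * dt[i - 1L])
    }
  }
  h
}

#' Derive an accelerometer series from a skeleton stream
#'
#' Emits the vertical-acceleration magnitude a body-worn sensor would roughly
#' report for one joint: `|g + d2h/dt2|` where `h` is the joint's height above
#' the floor plane.  At rest this is `g`; in free fall it approaches 0.  Used
#' to exercise the accelerometer replay adapter end-to-end.
#'
#' @param stream a `skeleton_stream` with at least 3 frames.
#' @param joint joint name (default `"head"`).
#' @param g standard gravity, m/s^2.
#' @return an `acceleration_series` data frame.
#' @export
accelerometer_series <- function(stream, joint = "head", g = 9.81) {
  stopifnot(inherits(stream, "skeleton_stream"), n_frames(stream) >= 3L)
  h <- joint_height_series(stream, joint)
  t <- stream$frames$t
  n <- length(h)
  acc <- rep(NA_real_, n)
  dt <- diff(t)
  acc[2:(n - 1)] <- (h[3:n] - 2 * h[2:(n - 1)] + h[1:(n - 2)]) /
    (dt[-1] * dt[-length(dt)])
  acc[1] <- acc[2]
  acc[n] <- acc[n - 1]
  structure(data.frame(t = t, a_mag = abs(g + acc)),
            class = c("acceleration_series", "data.frame"))
}
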