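# Per-frame kinematics: height above the floor plane, movement direction,
# irregular-movement distance, speed and acceleration.

joint_xyz <- function(joint) {
  if (inherits(joint, "joint_position")) {
    if (identical(joint$state, "not_tracked")) return(NULL)
    c(joint$x, joint$y, joint$z)
  } else if (is.numeric(joint) && length(joint) == 3L) {
    as.numeric(joint)
  } else {
    stop("joint must be a joint_position or numeric xyz triple",
         call. = FALSE)
  }
}

#' Height of a joint above the floor plane
#'
#' Point-to-plane distance `|Ax + By + Cz + D| / sqrt(A^2 + B^2 + C^2)` from
#' a joint to the floor-clipping plane.  Invariant to positive scaling of the
#' plane vector.
#'
#' @param joint a [joint_position()] or numeric `c(x, y, z)`.
#' @param plane a [floor_plane()] or numeric `c(A, B, C, D)`.
#' @return height in meters (non-negative), or `NA_real_` if the joint is not
#'   tracked.
#' @examples
#' joint_height(c(0, 1.5, 2), floor_plane(0, 1, 0, 0))   # 1.5
#' joint_height(c(0, 0.59, 2), floor_plane(0, 1, 0, 0.91)) # 1.5
#' @export
joint_height <- function(joint, plane) {
  p <- as.numeric(plane)
  if (length(p) != 4L || !all(is.finite(p))) {
    stop("plane must be numeric (A, B, C, D)", call. = FALSE)
  }
  nrm <- sqrt(sum(p[1:3]^2))
  if (nrm == 0) stop("degenerate floor plane (A = B = C = 0)", call. = FALSE)
  v <- joint_xyz(joint)
  if (is.null(v)) return(NA_real_)
  abs(sum(p[1:3] * v) + p[4]) / nrm
}

# Vectorized height of one named joint over every frame of a stream;
# NA where the joint is not tracked.
joint_height_series <- function(stream, joint) {
  fr <- stream$frames
  nrm <- sqrt(fr$floor_A^2 + fr$floor_B^2 + fr$floor_C^2)
  h <- abs(fr$floor_A * fr[[paste0(joint, "_x")]] +
           fr$floor_B * fr[[paste0(joint, "_y")]] +
           fr$floor_C * fr[[paste0(joint, "_z")]] + fr$floor_D) / nrm
  h[fr[[paste0(joint, "_state")]] == "not_tracked"] <- NA_real_
  h
}

#' Classify the direction of a movement
#'
#' A displacement is `stationary` below `epsilon`, `axis_x`/`axis_y`/`axis_z`
#' when the dominant axis carries at least the `dominance` fraction of the
#' Euclidean displacement (ties at the boundary classify as axis-aligned),
#' and `irregular` otherwise.
#'
#' @param prev,curr joint positions ([joint_position()] or numeric xyz).
#' @param epsilon stationarity threshold, meters per sample.
#' @param dominance axis share of the Euclidean displacement, in (0, 1].
#' @return one of `"stationary"`, `"axis_x"`, `"axis_y"`, `"axis_z"`,
#'   `"irregular"`.
#' @export
movement_direction <- function(prev, curr, epsilon = 0.01, dominance = 0.8) {
  d <- joint_xyz(curr) - joint_xyz(prev)
  len <- sqrt(sum(d^2))
  if (len < epsilon) return("stationary")
  k <- which.max(abs(d))
  if (abs(d[k]) / len >= dominance) c("axis_x", "axis_y", "axis_z")[k]
  else "irregular"
}

#' Distance travelled by an irregular (off-axis) movement
#'
#' Euclidean length of the in-plane displacement,
#' `sqrt((x - x')^2 + (y - y')^2)`; the depth axis can be included via
#' `include_z`.
#'
#' @param prev,curr joint positions ([joint_position()] or numeric xyz).
#' @param include_z include the depth (z) displacement as well.
#' @return distance in meters; symmetric in argument order.
#' @export
irregular_distance <- function(prev, curr, include_z = FALSE) {
  d <- joint_xyz(curr) - joint_xyz(prev)
  if (include_z) sqrt(sum(d^2)) else sqrt(d[1]^2 + d[2]^2)
}

#' Instantaneous speed between two samples
#'
#' `|d_c - d_p| / (t_c - t_p)`.  With the skip-one sampling policy at
#' 30 frames/s the denominator is 1/15 s.
#'
#' @param d_c,d_p current and previous distance (or coordinate), meters.
#' @param t_c,t_p current and previous time, seconds (`t_c > t_p`).
#' @return speed in m/s (non-negative).
#' @export
instantaneous_speed <- function(d_c, d_p, t_c, t_p) {
  if (t_c <= t_p) stop("t_c must be greater than t_p", call. = FALSE)
  abs(d_c - d_p) / (t_c - t_p)
}

frame_joint_ok <- function(frame, joint) {
  j <- frame$joints[[joint]]
  !is.null(j) && j$state != "not_tracked"
}

#' Derive one kinematic sample from a short frame buffer
#'
#' Given the last 2–3 frames, computes joint heights, the movement direction
#' of the tracking joint, the displacement (axis difference when axis-aligned,
#' in-plane Euclidean distance when irregular), the speed, and — when three
#' frames are available — the acceleration as the change of speed over the
#' sample interval.
#'
#' @param frames list of 2 or 3 `skeleton_frame` objects (oldest first),
#'   typically spaced by the skip policy.
#' @param joint_set joint names whose heights are reported.
#' @param config an [fs_config()].
#' @return a `kinematic_sample` list (`frame_index`, `heights`, `direction`,
#'   `displacement`, `speed`, `acceleration`), or `NULL` when fewer than two
#'   usable frames are supplied (the detector treats this as a skipped frame).
#' @export
kinematic_sample <- function(frames,
                             joint_set = c("head", "shoulder_center",
                                           "hip_center"),
                             config = fs_config()) {
  config <- as_fs_config(config)
  if (length(frames) < 2L) return(NULL)
  cf <- frames[[length(frames)]]
  pf <- frames[[length(frames) - 1L]]
  track <- config$joints$tracking
  key <- config$joints$key
  if (!all(vapply(key, frame_joint_ok, logical(1), frame = cf)) ||
      !all(vapply(key, frame_joint_ok, logical(1), frame = pf))) {
    return(NULL)
  }
  heights <- vapply(joint_set, function(j) {
    if (frame_joint_ok(cf, j)) joint_height(cf$joints[[j]], cf$floor)
    else NA_real_
  }, numeric(1))
  p0 <- cf$joints[[track]]
  p1 <- pf$joints[[track]]
  dir <- movement_direction(p1, p0, config$kinematics$stationary_eps,
                            config$kinematics$dominance)
  disp <- switch(dir,
    stationary = 0,
    axis_x = abs(p0$x - p1$x),
    axis_y = abs(p0$y - p1$y),
    axis_z = abs(p0$z - p1$z),
    irregular = irregular_distance(p1, p0, config$kinematics$irregular_3d))
  speed <- disp / (cf$t - pf$t)
  accel <- NA_real_
  if (length(frames) >= 3L) {
    prev <- kinematic_sample(frames[seq_len(length(frames) - 1L)],
                             joint_set, config)
    if (!is.null(prev)) {
      accel <- (speed - prev$speed) / (cf$t - pf$t)
    }
  }
  structure(list(frame_index = cf$frame_index, heights = heights,
                 direction = dir, displacement = disp, speed = speed,
                 acceleration = accel),
            class = "kinematic_sample")
}

runmed_na <- function(x, k) {
  if (k <= 1L) return(x)
  ok <- !is.na(x)
  if (sum(ok) >= k) x[ok] <- stats::runmed(x[ok], k, endrule = "median")
  x
}

lagged_speed <- function(px, py, pz, t, lag) {
  n <- length(t)
  s <- rep(NA_real_, n)
  if (n > lag) {
    i <- (lag + 1L):n
    d <- sqrt((px[i] - px[i - lag])^2 + (py[i] - py[i - lag])^2 +
              (pz[i] - pz[i - lag])^2)
    s[i] <- d / (t[i] - t[i - lag])
  }
  s
}

#' Per-frame kinematics of a whole stream
#'
#' Vectorized derivation of everything the detector consumes: heights of the
#' key joints above the floor plane, the movement direction of the tracking
#' joint, head-channel speed under the skip policy (and a fine every-frame
#' speed for the intensive-monitoring path), and the smoothed acceleration.
#' Speeds use the full 3-D displacement of the joint, so both horizontal
#' locomotion and vertical drops register.
#'
#' @param stream a `skeleton_stream` with at least 2 frames.
#' @param config an [fs_config()].
#' @return data frame with one row per frame: `frame`, `t`, `subject`
#'   (key joints tracked), `h_head`, `h_shoulder_center`, `h_hip_center`,
#'   `direction`, `speed`, `fine_speed`, `accel`.  Leading entries that need
#'   unavailable history are `NA`.
#' @export
compute_kinematics <- function(stream, config = fs_config()) {
  config <- as_fs_config(config)
  stopifnot(inherits(stream, "skeleton_stream"))
  fr <- stream$frames
  n <- nrow(fr)
  if (n < 2L) stop("kinematics require at least 2 frames", call. = FALSE)
  t <- fr$t
  lag <- config$kinematics$skip + 1L

  key <- config$joints$key
  subject <- Reduce(`&`, lapply(key, function(j) {
    fr[[paste0(j, "_state")]] != "not_tracked"
  }))

  h_head <- joint_height_series(stream, "head")
  h_sc <- joint_height_series(stream, "shoulder_center")
  h_hc <- joint_height_series(stream, "hip_center")

  # head channel: 3-D displacement speed under the skip policy
  speed <- lagged_speed(fr$head_x, fr$head_y, fr$head_z, t, lag)
  speed <- runmed_na(speed, config$kinematics$speed_smooth)
  fine_speed <- lagged_speed(fr$head_x, fr$head_y, fr$head_z, t, 1L)
  fine_speed <- runmed_na(fine_speed, config$kinematics$fine_speed_smooth)

  accel <- rep(NA_real_, n)
  i <- which(!is.na(speed))
  if (length(i) > lag) {
    j <- i[i > min(i) + lag - 1L]
    accel[j] <- (speed[j] - speed[j - lag]) / (t[j] - t[j - lag])
  }
  accel <- runmed_na(accel, config$kinematics$accel_smooth)

  # movement direction of the tracking joint
  track <- config$joints$tracking
  tx <- fr[[paste0(track, "_x")]]
  ty <- fr[[paste0(track, "_y")]]
  tz <- fr[[paste0(track, "_z")]]
  direction <- rep(NA_character_, n)
  if (n > lag) {
    i <- (lag + 1L):n
    dx <- tx[i] - tx[i - lag]
    dy <- ty[i] - ty[i - lag]
    dz <- tz[i] - tz[i - lag]
    len <- sqrt(dx^2 + dy^2 + dz^2)
    amax <- pmax(abs(dx), abs(dy), abs(dz))
    ax <- max.col(cbind(abs(dx), abs(dy), abs(dz)), ties.method = "first")
    dir <- ifelse(len < config$kinematics$stationary_eps, "stationary",
           ifelse(amax / len >= config$kinematics$dominance,
                  c("axis_x", "axis_y", "axis_z")[ax], "irregular"))
    direction[i] <- dir
  }

  data.frame(frame = fr$frame, t = t, subject = subject,
             h_head = h_head, h_shoulder_center = h_sc, h_hip_center = h_hc,
             direction = direction, speed = speed, fine_speed = fine_speed,
             accel = accel, stringsAsFactors = FALSE)
}
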