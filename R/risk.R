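# Gait-derived fall-risk factors and the low/high risk level that selects
# the detector's monitoring path.
#
# The three factors compare a previous frame (PF) and a current frame (CF):
#   step symmetry — change in the lateral separation of the two feet, taken
#     on the movement axis;
#   trunk sway    — lateral offset of the torso from the hip midpoint,
#     averaged over the two frames, taken on the axis orthogonal to the
#     movement;
#   arm spread    — change in the mean torso-to-arm lateral distance,
#     positive when the arms are opening.

movement_axis <- function(direction, pf, cf, config) {
  if (identical(direction, "axis_x")) return(list(axis = "x", caveat = FALSE))
  if (identical(direction, "axis_z")) return(list(axis = "z", caveat = FALSE))
  # irregular / stationary / vertical: fall back to the dominant ground axis
  track <- config$joints$tracking
  dx <- abs(cf$joints[[track]]$x - pf$joints[[track]]$x)
  dz <- abs(cf$joints[[track]]$z - pf$joints[[track]]$z)
  list(axis = if (dz >= dx) "z" else "x", caveat = TRUE)
}

lateral_axis <- function(axis) if (axis == "z") "x" else "z"

axis_val <- function(frame, joint, axis) frame$joints[[joint]][[axis]]

#' Step symmetry between two frames
#'
#' Difference of the unsigned foot separations (right minus left, as a
#' distance) between the previous and current frame, measured on the movement
#' axis: x-values when walking along x, z-values when walking along z.  For a
#' periodic gait sampled at successive step extremes this equals the
#' left/right step-length inequality.
#'
#' @param pf,cf previous and current `skeleton_frame` (see [get_frame()]).
#' @param direction movement direction label (`"axis_x"`, `"axis_z"`, or any
#'   other label, which falls back to the dominant ground axis with a caveat
#'   attribute).
#' @param config an [fs_config()].
#' @return meters (sign preserved), or `NA_real_` if a foot is untracked.
#' @export
step_symmetry <- function(pf, cf, direction, config = fs_config()) {
  config <- as_fs_config(config)
  ok <- all(vapply(c("foot_l", "foot_r"), frame_joint_ok, logical(1),
                   frame = pf)) &&
        all(vapply(c("foot_l", "foot_r"), frame_joint_ok, logical(1),
                   frame = cf))
  if (!ok) return(NA_real_)
  ax <- movement_axis(direction, pf, cf, config)
  sep <- function(f) abs(axis_val(f, "foot_r", ax$axis) -
                         axis_val(f, "foot_l", ax$axis))
  structure(sep(pf) - sep(cf), caveat = if (ax$caveat) "dominant-axis fallback")
}

#' Trunk sway between two frames
#'
#' Average over the two frames of the torso's lateral offset from the hip
#' midpoint, measured on the axis orthogonal to the movement (x when walking
#' along z, z when walking along x).  Sign preserved; a left-leaning posture
#' negates a right-leaning one.
#'
#' @inheritParams step_symmetry
#' @return meters, or `NA_real_` if torso or a hip is untracked.
#' @export
trunk_sway <- function(pf, cf, direction, config = fs_config()) {
  config <- as_fs_config(config)
  torso <- config$joints$alias$torso
  need <- c(torso, "hip_l", "hip_r")
  ok <- all(vapply(need, frame_joint_ok, logical(1), frame = pf)) &&
        all(vapply(need, frame_joint_ok, logical(1), frame = cf))
  if (!ok) return(NA_real_)
  ax <- movement_axis(direction, pf, cf, config)
  lat <- lateral_axis(ax$axis)
  off <- function(f) {
    axis_val(f, torso, lat) -
      (axis_val(f, "hip_l", lat) + axis_val(f, "hip_r", lat)) / 2
  }
  structure((off(pf) + off(cf)) / 2,
            caveat = if (ax$caveat) "dominant-axis fallback")
}

#' Arm spread change between two frames
#'
#' Mean of the two torso-to-arm lateral distances in the current frame minus
#' the same in the previous frame; positive when the arms are opening (a
#' balance-recovery gesture).  Arm joints default to the hands (the distal
#' proxy for whole-arm spread) via the joint-alias table.
#'
#' @inheritParams step_symmetry
#' @return meters, or `NA_real_` if torso or an arm joint is untracked.
#' @export
spread_arm <- function(pf, cf, direction, config = fs_config()) {
  config <- as_fs_config(config)
  torso <- config$joints$alias$torso
  arm_l <- config$joints$alias$arm_l
  arm_r <- config$joints$alias$arm_r
  need <- c(torso, arm_l, arm_r)
  ok <- all(vapply(need, frame_joint_ok, logical(1), frame = pf)) &&
        all(vapply(need, frame_joint_ok, logical(1), frame = cf))
  if (!ok) return(NA_real_)
  ax <- movement_axis(direction, pf, cf, config)
  lat <- lateral_axis(ax$axis)
  d <- function(f) {
    (abs(axis_val(f, torso, lat) - axis_val(f, arm_r, lat)) +
     abs(axis_val(f, torso, lat) - axis_val(f, arm_l, lat))) / 2
  }
  structure(d(cf) - d(pf), caveat = if (ax$caveat) "dominant-axis fallback")
}

# Alternating extrema of a (smoothed) 1-D signal with a minimum excursion.
find_step_extrema <- function(s, min_amp) {
  n <- length(s)
  if (n < 5L) return(integer(0))
  ds <- diff(s)
  sgn <- sign(ds)
  # carry the last non-zero slope sign through flats; leading flats take the
  # first real slope so the boundary is not a fake extremum
  nz <- which(sgn != 0)
  if (length(nz) == 0L) return(integer(0))
  if (nz[1L] > 1L) sgn[seq_len(nz[1L] - 1L)] <- sgn[nz[1L]]
  for (i in seq_along(sgn)) if (sgn[i] == 0 && i > 1L) sgn[i] <- sgn[i - 1L]
  cand <- which(diff(sgn) != 0) + 1L
  if (length(cand) == 0L) return(integer(0))
  kept <- cand[1L]
  for (k in cand[-1L]) {
    if (abs(s[k] - s[kept[length(kept)]]) >= min_amp) kept <- c(kept, k)
  }
  kept
}

#' Per-frame fall-risk factor samples over a stream
#'
#' Computes trunk-sway and arm-spread samples at every frame (PF/CF spaced by
#' `risk$frame_lag`), and step-symmetry samples at successive step extremes
#' of the signed foot-separation signal (the instants at which the foot
#' separation equals a step length).  The movement axis is taken from the
#' per-frame direction classification, carried forward through stationary or
#' irregular frames.
#'
#' @param stream a `skeleton_stream`.
#' @param config an [fs_config()].
#' @param kin optional precomputed [compute_kinematics()] result.
#' @return data frame with one row per frame: `frame`, `t`, `axis`,
#'   `step_symmetry` (`NA` except at step extremes), `trunk_sway`,
#'   `spread_arm`.
#' @export
risk_factor_series <- function(stream, config = fs_config(), kin = NULL) {
  config <- as_fs_config(config)
  fr <- stream$frames
  n <- nrow(fr)
  if (is.null(kin)) kin <- compute_kinematics(stream, config)
  lagk <- config$risk$frame_lag

  # movement axis per frame, carried forward (default depth axis); the axis
  # only switches after a sustained run of frames on the other axis, so an
  # isolated jitter-driven classification cannot flip it
  axis <- character(n)
  last <- "z"
  cx <- cz <- 0L
  for (i in seq_len(n)) {
    d <- kin$direction[i]
    cx <- if (!is.na(d) && d == "axis_x") cx + 1L else 0L
    cz <- if (!is.na(d) && d == "axis_z") cz + 1L else 0L
    if (cx >= 5L) last <- "x"
    if (cz >= 5L) last <- "z"
    axis[i] <- last
  }
  lat <- ifelse(axis == "z", "x", "z")

  # locomotion flag: the tracking joint must be translating along the
  # carried axis both behind and ahead of the frame; step-symmetry samples
  # are only meaningful while the subject is actually stepping
  track <- config$joints$tracking
  loco_lag <- config$risk$loco_lag
  col0 <- function(j, a) fr[[paste0(j, "_", a)]]
  along <- ifelse(axis == "x", col0(track, "x"), col0(track, "z"))
  disp_back <- rep(NA_real_, n)
  disp_fwd <- rep(NA_real_, n)
  if (n > loco_lag) {
    i <- (loco_lag + 1L):n
    disp_back[i] <- abs(along[i] - along[i - loco_lag])
    disp_fwd[i - loco_lag] <- disp_back[i]
  }
  walking <- !is.na(disp_back) & !is.na(disp_fwd) &
    disp_back >= config$risk$loco_min_disp &
    disp_fwd >= config$risk$loco_min_disp

  pick <- function(j, a) {
    # value of joint j on per-frame axis vector a ("x"/"z" per frame)
    ifelse(a == "x", col0(j, "x"), col0(j, "z"))
  }
  torso <- config$joints$alias$torso
  arm_l <- config$joints$alias$arm_l
  arm_r <- config$joints$alias$arm_r

  off <- pick(torso, lat) - (pick("hip_l", lat) + pick("hip_r", lat)) / 2
  armd <- (abs(pick(torso, lat) - pick(arm_r, lat)) +
           abs(pick(torso, lat) - pick(arm_l, lat))) / 2

  sway <- rep(NA_real_, n)
  arm <- rep(NA_real_, n)
  if (n > lagk) {
    i <- (lagk + 1L):n
    sway[i] <- (off[i] + off[i - lagk]) / 2
    arm[i] <- armd[i] - armd[i - lagk]
  }

  # signed foot separation on the movement axis; step extremes give the
  # step-symmetry samples
  sep <- pick("foot_r", axis) - pick("foot_l", axis)
  sep_s <- runmed_na(sep, config$risk$sep_smooth)
  ext <- find_step_extrema(sep_s, config$risk$step_min_amp)
  stepsym <- rep(NA_real_, n)
  if (length(ext) >= 2L) {
    for (k in 2:length(ext)) {
      if (walking[ext[k]] && walking[ext[k - 1L]]) {
        stepsym[ext[k]] <- abs(sep_s[ext[k - 1L]]) - abs(sep_s[ext[k]])
      }
    }
  }

  data.frame(frame = fr$frame, t = fr$t, axis = axis,
             step_symmetry = stepsym, trunk_sway = sway, spread_arm = arm,
             stringsAsFactors = FALSE)
}

aggregate_factor <- function(x, how) {
  x <- x[!is.na(x)]
  if (length(x) == 0L) return(NA_real_)
  if (how == "max_abs") max(abs(x)) else mean(abs(x))
}

#' Assess the fall-risk level over a window of factor samples
#'
#' Aggregates each factor over the window (mean of absolute values by
#' default) and flags the subject `high` risk when any aggregate exceeds its
#' threshold (OR rule: any gait abnormality triggers intensive monitoring).
#'
#' @param window data frame of factor samples (as produced by
#'   [risk_factor_series()]), at least `risk$window_frames` rows for a full
#'   assessment.
#' @param config an [fs_config()].
#' @return a `risk_assessment` list: `level` (`"low"`/`"high"`),
#'   `aggregates`, `thresholds`, `exceeded`, `n`, and `insufficient` — `TRUE`
#'   when the window is shorter than required, in which case the level falls
#'   back to `"low"` (the caller should treat this as a caveat, not a
#'   clearance).
#' @export
assess_risk <- function(window, config = fs_config()) {
  config <- as_fs_config(config)
  stopifnot(is.data.frame(window))
  thr <- unlist(config$risk$threshold)
  how <- config$risk$aggregate
  agg <- c(
    step_symmetry = aggregate_factor(window$step_symmetry, how),
    trunk_sway = aggregate_factor(window$trunk_sway, how),
    spread_arm = aggregate_factor(window$spread_arm, how))
  insufficient <- nrow(window) < config$risk$window_frames
  exceeded <- !is.na(agg) & agg > thr[names(agg)]
  level <- if (!insufficient && any(exceeded)) "high" else "low"
  structure(list(level = level, aggregates = agg,
                 thresholds = thr[names(agg)], exceeded = exceeded,
                 n = nrow(window), insufficient = insufficient),
            class = "risk_assessment")
}

#' @export
print.risk_assessment <- function(x, ...) {
  cat(sprintf("<risk_assessment> level = %s%s (n = %d samples)\n", x$level,
              if (x$insufficient) " [insufficient window]" else "", x$n))
  for (f in names(x$aggregates)) {
    cat(sprintf("  %-14s %8.4f m  (threshold %.2f%s)\n", f,
                x$aggregates[[f]], x$thresholds[[f]],
                if (isTRUE(x$exceeded[[f]])) ", exceeded" else ""))
  }
  invisible(x)
}

#' Assess the fall-risk level of a whole stream
#'
#' Convenience wrapper: computes the factor series and assesses risk over the
#' full stream as one window.
#'
#' @inheritParams risk_factor_series
#' @return a `risk_assessment`.
#' @export
assess_stream_risk <- function(stream, config = fs_config()) {
  config <- as_fs_config(config)
  assess_risk(risk_factor_series(stream, config), config)
}

# Rolling (causal) risk level per frame, vectorized; used by the detector.
risk_level_series <- function(factors, config) {
  n <- nrow(factors)
  w <- config$risk$window_frames
  thr <- unlist(config$risk$threshold)
  roll_mean_abs <- function(x) {
    v <- abs(x)
    cnt <- cumsum(!is.na(v))
    v[is.na(v)] <- 0
    cs <- cumsum(v)
    num <- cs - c(rep(0, w), head(cs, -w))
    den <- cnt - c(rep(0, w), head(cnt, -w))
    ifelse(den > 0, num / den, NA_real_)
  }
  agg <- cbind(step_symmetry = roll_mean_abs(factors$step_symmetry),
               trunk_sway = roll_mean_abs(factors$trunk_sway),
               spread_arm = roll_mean_abs(factors$spread_arm))
  filled <- seq_len(n) >= w
  high <- filled & (
    (!is.na(agg[, 1]) & agg[, 1] > thr[["step_symmetry"]]) |
    (!is.na(agg[, 2]) & agg[, 2] > thr[["trunk_sway"]]) |
    (!is.na(agg[, 3]) & agg[, 3] > thr[["spread_arm"]]))
  list(high = high, aggregates = agg, filled = filled)
}
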