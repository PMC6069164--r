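# Seeded synthetic skeleton-motion generator.
#
# Stylized, channel-based kinematics: each activity segment drives a small
# set of scalar channels (head height, lateral lean, signed foot separation,
# extra arm spread, along-axis body position), from which the 20-joint
# skeleton is synthesized and Gaussian sensor jitter added.  Piecewise-smooth
# trajectories, not biomechanics: the detector only needs the drop/velocity
# structure of the motion, not anatomically exact joints.

STAND <- list(
  head = 1.65, shoulder_center = 1.45, torso = 1.15, hip_center = 0.95,
  shoulder_l = 1.43, shoulder_r = 1.43, elbow_l = 1.15, elbow_r = 1.15,
  wrist_l = 0.95, wrist_r = 0.95, hand_l = 0.90, hand_r = 0.90,
  hip_l = 0.93, hip_r = 0.93, knee_l = 0.50, knee_r = 0.50,
  ankle_l = 0.10, ankle_r = 0.10, foot_l = 0.05, foot_r = 0.05)

sim_activities <- c("stand", "walk", "run", "sit_chair", "sit_floor",
                    "lie_floor", "pick_object", "fall_forward",
                    "fall_from_chair", "fall_while_sitting_down", "rest")

#' Gait parameter presets
#'
#' Walking styles for the simulator: `normal` (symmetric steps, 0.02 m
#' sway), `slow` (shorter, slower steps), and `weak` (0.2 m left/right
#' step-length asymmetry and 0.1 m trunk sway — the elderly-with-weak-gait
#' style the risk assessor must flag).
#'
#' @param preset `"normal"`, `"slow"` or `"weak"`.
#' @param ... individual overrides: `step_length_l`, `step_length_r` (m),
#'   `sway_amp` (m), `arm_spread_amp` (m), `cadence` (steps/s), `noise_sd`
#'   (m, per-coordinate sensor jitter).
#' @return a `gait_params` list.
#' @export
gait_params <- function(preset = c("normal", "slow", "weak"), ...) {
  preset <- match.arg(preset)
  p <- switch(preset,
    normal = list(step_length_l = 0.55, step_length_r = 0.55,
                  sway_amp = 0.02, arm_spread_amp = 0.02, cadence = 1.8,
                  noise_sd = 0.01),
    slow = list(step_length_l = 0.40, step_length_r = 0.40,
                sway_amp = 0.03, arm_spread_amp = 0.02, cadence = 1.1,
                noise_sd = 0.01),
    weak = list(step_length_l = 0.55, step_length_r = 0.35,
                sway_amp = 0.10, arm_spread_amp = 0.10, cadence = 1.2,
                noise_sd = 0.01))
  over <- list(...)
  p[names(over)] <- over
  stopifnot(all(unlist(p) >= 0))
  p$preset <- preset
  structure(p, class = "gait_params")
}

#' Build a motion script
#'
#' An ordered list of activity segments with gait parameters and a seed; the
#' simulator is deterministic given the script.
#'
#' @param segments list of segments, each `list(activity =, duration =,
#'   params = list(...))`; activities: stand, walk, run, sit_chair,
#'   sit_floor, lie_floor, pick_object, fall_forward, fall_from_chair,
#'   fall_while_sitting_down, rest.  Durations in seconds (> 0).
#' @param gait a [gait_params()] object.
#' @param seed integer RNG seed.
#' @param fps frames per second.
#' @param camera_height camera height above the floor, meters (the floor
#'   plane is `(0, 1, 0, camera_height)` throughout).
#' @param axis movement axis, `"z"` (toward/away from the sensor) or `"x"`.
#' @return a `motion_script` list.
#' @export
motion_script <- function(segments, gait = gait_params(), seed = 1L,
                          fps = 30, camera_height = 0.91, axis = c("z", "x")) {
  axis <- match.arg(axis)
  for (seg in segments) {
    if (is.null(seg$activity) || !(seg$activity %in% sim_activities)) {
      stop("unknown activity: ", seg$activity, call. = FALSE)
    }
    if (is.null(seg$duration) || seg$duration <= 0) {
      stop("segment durations must be > 0", call. = FALSE)
    }
  }
  structure(list(segments = segments, gait = gait, seed = as.integer(seed),
                 fps = fps, camera_height = camera_height, axis = axis),
            class = "motion_script")
}

# blend a channel from its previous end value into the segment target over
# ~0.45 s, so segment boundaries do not create velocity spikes
blend_in <- function(from, target, fps, tblend = 0.45) {
  n <- length(target)
  k <- min(n, max(1L, round(tblend * fps)))
  w <- c(seq(0, 1, length.out = k), rep(1, n - k))
  from * (1 - w) + target * w
}

is_fall_activity <- function(a) startsWith(a, "fall")

# One activity segment -> channel target vectors (pre-blend).  `state` holds
# h (head height), pos (unfolded along-axis position), phase, lean, sep, armx.
segment_channels <- function(activity, dur, gait, state, params, fps) {
  n <- max(2L, round(dur * fps))
  tt <- seq_len(n) / fps
  ch <- list(h = rep(state$h, n), lean = rep(0, n), sep = rep(0.1, n),
             armx = rep(0, n), pos = rep(state$pos, n))
  phase_end <- state$phase

  gait_like <- function(g) {
    f_s <- g$cadence / 2
    # start the gait cycle at the phase matching the current foot
    # separation, so entering a walk does not fake a step-length change
    ph0 <- if (state$sep >= 0) {
      asin(min(1, state$sep / max(g$step_length_r, 1e-6)))
    } else {
      -asin(min(1, -state$sep / max(g$step_length_l, 1e-6)))
    }
    ph <- ph0 + 2 * pi * f_s * tt
    s <- sin(ph)
    bob <- if (is.null(params$bob)) 0.03 else params$bob
    list(
      h = STAND$head + bob * sin(2 * ph),
      lean = g$sway_amp * sin(ph),
      sep = ifelse(s >= 0, g$step_length_r, g$step_length_l) * s,
      armx = g$arm_spread_amp * sin(ph + 1),
      pos = state$pos +
        cumsum(rep(g$cadence * (g$step_length_l + g$step_length_r) / 2 / fps,
                   n)),
      phase = ph[n])
  }
  descend <- function(target, descent_s) {
    # raised-cosine descent from the current height, then rest at target
    frac <- pmin(1, tt / max(descent_s, 1 / fps))
    target + (state$h - target) * (1 + cos(pi * frac)) / 2
  }
  drop_then_settle <- function(target, drop_frac = 0.45) {
    # accelerating (quadratic) drop, then a small decaying bounce: the
    # velocity profile of an unbroken fall followed by impact
    t1 <- drop_frac * dur
    h <- ifelse(tt <= t1,
                state$h - (state$h - target) * (tt / t1)^2,
                target + 0.06 * exp(-3 * (tt - t1)) *
                  abs(sin(12 * (tt - t1))))
    h
  }

  if (activity %in% c("walk", "run")) {
    g <- gait
    if (activity == "run") {
      g <- gait
      g$step_length_l <- g$step_length_r <- 0.9
      g$cadence <- 3
      if (is.null(params$bob)) params$bob <- 0.05
    }
    w <- gait_like(g)
    ch$h <- w$h
    ch$lean <- w$lean
    ch$sep <- w$sep
    ch$armx <- w$armx
    ch$pos <- w$pos
    phase_end <- w$phase
  } else if (activity == "stand") {
    ch$h <- rep(STAND$head, n)
  } else if (activity == "rest") {
    # hold everything where it is
  } else if (activity == "sit_chair") {
    ch$h <- descend(1.20, min(1.5, 0.6 * dur))
  } else if (activity == "sit_floor") {
    ds <- if (is.null(params$descent_s)) min(3.0, 0.8 * dur)
          else min(params$descent_s, dur)
    ch$h <- descend(0.70, ds)
  } else if (activity == "lie_floor") {
    ds <- if (is.null(params$descent_s)) min(3.7, dur)
          else min(params$descent_s, dur)
    ch$h <- descend(0.25, ds)
  } else if (activity == "pick_object") {
    t1 <- 0.4 * dur; t2 <- 0.6 * dur
    frac <- ifelse(tt <= t1, tt / t1, ifelse(tt <= t2, 1, (dur - tt) /
                                             (dur - t2)))
    ch$h <- state$h - (state$h - 0.90) * (1 - cos(pi * pmin(1, frac))) / 2
  } else if (activity == "fall_forward" || activity == "fall_from_chair") {
    ch$h <- drop_then_settle(0.20)
    ch$pos <- state$pos + 0.3 * pmin(1, tt / (0.45 * dur))
  } else if (activity == "fall_while_sitting_down") {
    tA <- 0.4 * dur; tB <- 0.8 * dur
    hA <- 1.10
    h <- numeric(n)
    for (k in seq_len(n)) {
      if (tt[k] <= tA) {
        h[k] <- hA + (state$h - hA) * (1 + cos(pi * tt[k] / tA)) / 2
      } else if (tt[k] <= tB) {
        h[k] <- hA - (hA - 0.20) * ((tt[k] - tA) / (tB - tA))^2
      } else {
        h[k] <- 0.20 + 0.06 * exp(-3 * (tt[k] - tB)) *
          abs(sin(12 * (tt[k] - tB)))
      }
    }
    ch$h <- h
  } else {
    stop("unknown activity: ", activity, call. = FALSE)
  }

  # smooth channel hand-over from the previous segment; walking enters the
  # gait cycle at the matched phase, so its separation is already continuous
  ch$h <- blend_in(state$h, ch$h, fps)
  ch$lean <- blend_in(state$lean, ch$lean, fps)
  if (!(activity %in% c("walk", "run"))) {
    ch$sep <- blend_in(state$sep, ch$sep, fps)
  }
  ch$armx <- blend_in(state$armx, ch$armx, fps)

  state$h <- ch$h[n]
  state$pos <- ch$pos[n]
  state$phase <- phase_end
  state$lean <- ch$lean[n]
  state$sep <- ch$sep[n]
  state$armx <- ch$armx[n]
  list(channels = ch, state = state, n = n)
}

fold_path <- function(p, lo = 1.2, hi = 4.2) {
  w <- hi - lo
  q <- (p - lo) %% (2 * w)
  lo + ifelse(q > w, 2 * w - q, q)
}

# channels -> wide skeleton frame table
synthesize_frames <- function(ch, t, camera_height, axis, noise_sd) {
  n <- length(t)
  scale <- ch$h / STAND$head
  pos <- fold_path(ch$pos)
  lat0 <- list(
    head = 1.3 * ch$lean, shoulder_center = 1.3 * ch$lean,
    torso = ch$lean, hip_center = rep(0, n),
    shoulder_l = -0.18 + ch$lean, shoulder_r = 0.18 + ch$lean,
    elbow_l = -(0.22 + ch$armx) + ch$lean,
    elbow_r = (0.22 + ch$armx) + ch$lean,
    wrist_l = -(0.24 + ch$armx) + ch$lean,
    wrist_r = (0.24 + ch$armx) + ch$lean,
    hand_l = -(0.25 + ch$armx) + ch$lean,
    hand_r = (0.25 + ch$armx) + ch$lean,
    hip_l = rep(-0.12, n), hip_r = rep(0.12, n),
    knee_l = rep(-0.10, n), knee_r = rep(0.10, n),
    ankle_l = rep(-0.10, n), ankle_r = rep(0.10, n),
    foot_l = rep(-0.10, n), foot_r = rep(0.10, n))
  along0 <- list(knee_l = -ch$sep / 4, knee_r = ch$sep / 4,
                 ankle_l = -ch$sep / 2, ankle_r = ch$sep / 2,
                 foot_l = -ch$sep / 2, foot_r = ch$sep / 2)
  df <- data.frame(frame = seq_len(n) - 1L, t = t,
                   floor_A = rep(0, n), floor_B = rep(1, n),
                   floor_C = rep(0, n), floor_D = rep(camera_height, n))
  for (j in fs_joints()) {
    height <- pmax(0.03, STAND[[j]] * scale)
    along <- pos + (if (is.null(along0[[j]])) 0 else along0[[j]])
    lat <- lat0[[j]]
    if (axis == "z") {
      xx <- lat
      zz <- along
    } else {
      xx <- along
      zz <- lat
    }
    df[[paste0(j, "_x")]] <- xx + stats::rnorm(n, 0, noise_sd)
    df[[paste0(j, "_y")]] <- height - camera_height +
      stats::rnorm(n, 0, noise_sd)
    df[[paste0(j, "_z")]] <- pmax(0, zz + stats::rnorm(n, 0, noise_sd))
    df[[paste0(j, "_state")]] <- rep("tracked", n)
  }
  df
}

#' Simulate a labelled skeleton stream
#'
#' Deterministic given the script (the script's seed initializes the RNG).
#' Fall segments drive the head from its current height to near the floor
#' within the segment duration with an accelerating drop; walking produces a
#' small sinusoidal head-height fluctuation (0.03 m amplitude by default);
#' the floor plane is constant at `(0, 1, 0, camera_height)`.
#'
#' @param script a [motion_script()].
#' @return `list(stream = skeleton_stream, labels = data.frame(frame, t,
#'   activity, is_fall))`.
#' @export
simulate_motion <- function(script) {
  stopifnot(inherits(script, "motion_script"))
  set.seed(script$seed)
  fps <- script$fps
  state <- list(h = STAND$head, pos = 2.0, phase = 0, lean = 0, sep = 0.1,
                armx = 0)
  chans <- list(h = numeric(0), lean = numeric(0), sep = numeric(0),
                armx = numeric(0), pos = numeric(0))
  activity <- character(0)
  for (seg in script$segments) {
    out <- segment_channels(seg$activity, seg$duration, script$gait, state,
                            if (is.null(seg$params)) list() else seg$params,
                            fps)
    for (nm in names(chans)) chans[[nm]] <- c(chans[[nm]],
                                              out$channels[[nm]])
    activity <- c(activity, rep(seg$activity, out$n))
    state <- out$state
  }
  n <- length(chans$h)
  t <- (seq_len(n) - 1L) / fps
  df <- synthesize_frames(chans, t, script$camera_height, script$axis,
                          script$gait$noise_sd)
  stream <- skeleton_stream(df, fps = fps,
                            camera_height = script$camera_height,
                            source = sprintf("simulated(seed=%d)",
                                             script$seed))
  labels <- data.frame(frame = df$frame, t = t, activity = activity,
                       is_fall = is_fall_activity(activity),
                       stringsAsFactors = FALSE)
  list(stream = stream, labels = labels)
}

#' Standard evaluation suite
#'
#' A seeded set of 70 labelled scenarios mirroring a 30-fall / 40-ADL
#' benchmark composition: 30 fall sequences (forward falls, falls from a
#' chair, falls while sitting down, preceded by walking with a randomly
#' drawn gait style and fall durations drawn from 1.3–1.9 s) and 40
#' activities of daily living (walking, a running burst, sitting on a chair
#' or the floor, lying down slowly over 3.7–4.2 s, picking an object).
#' ADL sequences use the normal/slow gait styles (the benchmark's activities
#' were performed by healthy adults); weak gait appears in fall sequences.
#'
#' @param seed integer seed; the composition (30/40) is fixed, parameter
#'   draws are seed-dependent.
#' @return list of 70 scenarios, each `list(id, kind, is_fall, script)`;
#'   pass each `script` to [simulate_motion()].
#' @export
standard_suite <- function(seed) {
  set.seed(as.integer(seed))
  scen <- list()
  add <- function(kind, is_fall, segments, gait) {
    scen[[length(scen) + 1L]] <<- list(
      id = sprintf("%s_%02d", kind, length(scen) + 1L), kind = kind,
      is_fall = is_fall,
      script = motion_script(segments, gait = gait,
                             seed = sample.int(2^30, 1)))
  }
  fall_kinds <- rep(c("fall_forward", "fall_from_chair",
                      "fall_while_sitting_down"), c(12, 9, 9))
  for (fk in sample(fall_kinds)) {
    gp <- gait_params(sample(c("normal", "slow", "weak"), 1))
    w <- stats::runif(1, 2.5, 3.5)
    fd <- stats::runif(1, 1.3, 1.9)
    segs <- if (fk == "fall_from_chair") {
      list(list(activity = "walk", duration = w),
           list(activity = "sit_chair", duration = 2.0),
           list(activity = fk, duration = fd),
           list(activity = "rest", duration = 2.5))
    } else {
      list(list(activity = "walk", duration = w),
           list(activity = fk, duration = fd),
           list(activity = "rest", duration = 2.5))
    }
    add(fk, TRUE, segs, gp)
  }
  adl_kinds <- rep(c("walk_only", "run_burst", "sit_chair", "sit_floor",
                     "lie_floor", "pick_object"), c(8, 6, 6, 6, 8, 6))
  for (ak in sample(adl_kinds)) {
    gp <- gait_params(sample(c("normal", "slow"), 1))
    w <- stats::runif(1, 2.5, 3.5)
    segs <- switch(ak,
      walk_only = list(list(activity = "walk", duration = 8)),
      run_burst = list(list(activity = "walk", duration = 2.5),
                       list(activity = "run", duration = 2),
                       list(activity = "walk", duration = 2.5)),
      sit_chair = list(list(activity = "walk", duration = w),
                       list(activity = "sit_chair", duration = 3),
                       list(activity = "rest", duration = 1.5)),
      sit_floor = list(list(activity = "walk", duration = w),
                       list(activity = "sit_floor", duration = 4),
                       list(activity = "rest", duration = 1.5)),
      lie_floor = {
        ds <- stats::runif(1, 3.7, 4.2)
        list(list(activity = "walk", duration = w),
             list(activity = "lie_floor", duration = ds + 0.8,
                  params = list(descent_s = ds)),
             list(activity = "rest", duration = 2))
      },
      pick_object = list(list(activity = "walk", duration = w),
                         list(activity = "pick_object", duration = 2.5),
                         list(activity = "walk", duration = 2)))
    add(ak, FALSE, segs, gp)
  }
  scen
}
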