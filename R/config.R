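#' Analysis configuration
#'
#' Builds the nested configuration list used by every stage of the pipeline,
#' merging user overrides into the package defaults.  Values are grouped by
#' namespace: `joints` (vocabulary aliases and the tracking joint),
#' `kinematics` (frame-skip policy and classification tolerances), `risk`
#' (factor thresholds and aggregation window) and `detector` (the thresholds
#' of the five-process algorithm).
#'
#' Defaults of note (all lengths in meters, times in seconds):
#' \describe{
#'   \item{kinematics$skip}{1 — joint positions are compared two frames apart,
#'     giving the 1/15 s interval at 30 frames/s.}
#'   \item{kinematics$dominance}{0.8 — a displacement counts as axis-aligned
#'     when the dominant axis carries at least this fraction of the Euclidean
#'     displacement; ties at the boundary classify as axis-aligned.}
#'   \item{risk$threshold}{step_symmetry 0.10, trunk_sway 0.05,
#'     spread_arm 0.15; any windowed aggregate above its threshold flags the
#'     subject high-risk (OR rule).}
#'   \item{detector$velocity_high}{2.0 m/s; detector$near_floor_height 0.5 m —
#'     the operating point commonly used for head-channel fall detection.}
#' }
#'
#' @param ... named overrides, either nested lists (e.g.
#'   `detector = list(velocity_high = 1.8)`) or a single list in the same
#'   shape.
#' @return a nested list of class `fs_config`.
#' @examples
#' cfg <- fs_config(detector = list(velocity_high = 1.8))
#' cfg$detector$velocity_high
#' @export
fs_config <- function(...) {
  defaults <- list(
    joints = list(
      tracking = "shoulder_center",
      key = c("head", "shoulder_center", "hip_center"),
      alias = list(arm_l = "hand_l", arm_r = "hand_r", torso = "torso")
    ),
    kinematics = list(
      skip = 1L,              # frames skipped between compared positions
      stationary_eps = 0.01,  # m per sample below which motion is stationary
      dominance = 0.8,        # axis share of Euclidean displacement
      irregular_3d = FALSE,   # include depth axis in irregular distance
      speed_smooth = 3L,      # running-median width for the speed channel
      fine_speed_smooth = 5L, # wider smoothing for the noisier lag-1 speed
      accel_smooth = 3L       # running-median width for acceleration
    ),
    risk = list(
      window_frames = 60L,    # ~2 s at 30 fps
      frame_lag = 2L,         # PF/CF spacing for sway and arm-spread samples
      aggregate = "mean_abs", # or "max_abs"
      threshold = list(step_symmetry = 0.10, trunk_sway = 0.05,
                       spread_arm = 0.15),
      sep_smooth = 5L,        # running-median width for the foot-separation signal
      step_min_amp = 0.05,    # minimum excursion for a step extremum
      loco_lag = 10L,         # frames (~1/3 s) for the locomotion test
      loco_min_disp = 0.06    # m along-axis displacement that counts as walking
    ),
    detector = list(
      velocity_high = 2.0,
      near_floor_height = 0.5,
      confirm_window = 1.5,
      recovery_height = 0.8,
      acceleration_high = 10,
      buffer_seconds = 3,
      sensitive_velocity_factor = 0.75,
      sensitive_floor_factor = 1.25,
      slow_descent_seconds = 2.0,
      slow_descent_speed = 1.0,
      descent_rise_tol = 0.04,
      descent_rate_lag = 10L,  # frames (~1/3 s) over which descent rate is measured
      fluctuation_amp = 0.15,
      refractory_seconds = 0.5
    )
  )
  dots <- list(...)
  if (length(dots) == 1L && is.null(names(dots)) && is.list(dots[[1L]])) {
    dots <- dots[[1L]]
  }
  cfg <- merge_config(defaults, dots)
  stopifnot(cfg$detector$near_floor_height < cfg$detector$recovery_height)
  structure(cfg, class = "fs_config")
}

merge_config <- function(base, over) {
  if (length(over) == 0L) return(base)
  if (is.null(names(over)) || any(names(over) == "")) {
    stop("configuration overrides must be named", call. = FALSE)
  }
  for (nm in names(over)) {
    if (is.list(over[[nm]]) && is.list(base[[nm]])) {
      base[[nm]] <- merge_config(base[[nm]], over[[nm]])
    } else {
      base[[nm]] <- over[[nm]]
    }
  }
  base
}

#' Read a configuration file
#'
#' Reads a YAML file whose keys mirror the [fs_config()] namespaces and merges
#' it over the defaults.
#'
#' @param path path to a YAML file.
#' @return an `fs_config` object.
#' @export
read_config_yaml <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  fs_config(yaml::read_yaml(path))
}

as_fs_config <- function(config) {
  if (inherits(config, "fs_config")) config else fs_config(config)
}
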