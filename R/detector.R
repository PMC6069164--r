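# Two-stage, five-process fall detection.
#
# Stage 1 (candidate generation), per frame:
#   P1  subject present in the scene (key joints tracked)?
#   P2  compute kinematics + risk factors; an abnormally high velocity raises
#       a candidate immediately (-> P5).
#   P3  high-risk path: intensive monitoring with a finer-grained speed and a
#       more sensitive velocity / near-floor threshold pair.
#   P4  low-risk path: near-floor height with intentional-activity
#       recognition, or a high acceleration.
# Stage 2:
#   P5  confirmation: within the confirmation window the head must stay near
#       the floor with no recovery, show a sustained net drop rather than the
#       small up/down fluctuation of walking or running, corroborated by the
#       hip staying low.

#' Is a subject present in the frame?
#'
#' True iff the key joints (head, shoulder center, hip center by default) are
#' tracked.
#'
#' @param frame a `skeleton_frame` (see [get_frame()]).
#' @param config an [fs_config()].
#' @return logical.
#' @export
detect_subject <- function(frame, config = fs_config()) {
  config <- as_fs_config(config)
  if (length(frame$joints) == 0L) return(FALSE)
  all(vapply(config$joints$key, frame_joint_ok, logical(1), frame = frame))
}

#' Initial branch decision (Process 2)
#'
#' Routes a frame to the confirmation stage (high velocity), the high-risk
#' intensive path, or the normal path.
#'
#' @param speed head-channel speed under the skip policy, m/s.
#' @param risk_level `"low"` or `"high"`.
#' @param config an [fs_config()].
#' @return list with `branch` (`"to_P5"`, `"to_P3"`, `"to_P4"`) and
#'   `potential_fall` (logical: the velocity alert raised alongside the
#'   `to_P5` branch), or `NULL` if `speed` is `NA` (wait state).
#' @export
initial_assessment <- function(speed, risk_level, config = fs_config()) {
  config <- as_fs_config(config)
  if (is.na(speed)) return(NULL)
  if (speed > config$detector$velocity_high) {
    list(branch = "to_P5", potential_fall = TRUE)
  } else if (identical(risk_level, "high")) {
    list(branch = "to_P3", potential_fall = FALSE)
  } else {
    list(branch = "to_P4", potential_fall = FALSE)
  }
}

#' High-risk detection test (Process 3)
#'
#' Intensive monitoring for a high-risk subject: applies a lowered velocity
#' threshold to the fine (every-frame) speed and a raised near-floor height
#' threshold.
#'
#' @param fine_speed every-frame head speed, m/s.
#' @param head_height head height above the floor, meters.
#' @param config an [fs_config()].
#' @return logical: raise a potential-fall alert?
#' @export
risk_adapted_detection <- function(fine_speed, head_height,
                                   config = fs_config()) {
  config <- as_fs_config(config)
  d <- config$detector
  v_thr <- d$sensitive_velocity_factor * d$velocity_high
  h_thr <- d$sensitive_floor_factor * d$near_floor_height
  (!is.na(fine_speed) && fine_speed > v_thr) ||
    (!is.na(head_height) && head_height < h_thr)
}

#' Normal-path detection test (Process 4)
#'
#' For a low-risk subject at low velocity: a potential fall is flagged when
#' no intentional activity is recognized and either the head is below the
#' near-floor threshold or the acceleration is abnormally high.  An
#' intentional activity is a recognized slow descent (see Details of
#' [run_detector()]).
#'
#' @param head_height head height above the floor, meters.
#' @param acceleration smoothed head-channel acceleration, m/s^2.
#' @param intentional logical: is an intentional descent recognized?
#' @param config an [fs_config()].
#' @return logical: raise a potential-fall alert?
#' @export
normal_detection <- function(head_height, acceleration, intentional,
                             config = fs_config()) {
  config <- as_fs_config(config)
  d <- config$detector
  if (isTRUE(intentional)) return(FALSE)
  (!is.na(head_height) && head_height < d$near_floor_height) ||
    (!is.na(acceleration) && acceleration > d$acceleration_high)
}

# Recognize an intentional (slow, controlled) descent ending at frame i:
# over the last slow_descent_seconds the (trailing-mean) head height has
# been monotone non-increasing (rises above the running minimum of at most
# descent_rise_tol are tolerated, so sensor jitter does not break the run)
# and the vertical descent rate — measured over descent_rate_lag frames so
# jitter does not dominate the estimate — stayed below slow_descent_speed
# throughout: a controlled lowering of the body, as opposed to the short,
# fast drop of a fall.
intentional_descent <- function(i, t, hd, config) {
  d <- config$detector
  if (t[i] - t[1L] < d$slow_descent_seconds) return(FALSE)
  j0 <- which(t >= t[i] - d$slow_descent_seconds)[1L]
  w <- j0:i
  hw <- hd[w]
  if (anyNA(hw)) return(FALSE)
  runmin <- Inf
  for (v in hw) {
    if (v > runmin + d$descent_rise_tol) return(FALSE)
    runmin <- min(runmin, v)
  }
  lag <- d$descent_rate_lag
  k <- w[w - lag >= 1L]
  if (length(k) == 0L) return(FALSE)
  rate <- (hd[k - lag] - hd[k]) / (t[k] - t[k - lag])
  all(rate < d$slow_descent_speed, na.rm = TRUE)
}

#' Confirm or reject a potential fall (Process 5)
#'
#' Examines the confirmation window after a candidate.  The fall is confirmed
#' iff the head ends near the floor with no recovery above the recovery
#' height, the window shows a sustained net drop (at least the fluctuation
#' amplitude), the height pattern is not a small up/down oscillation (the
#' signature of walking or running: two or more derivative sign changes with
#' amplitude below the fluctuation threshold), and the hip corroborates by
#' also ending below the recovery height.
#'
#' @param candidate list with at least `t_start`, `source_process` and `id`.
#' @param window data frame covering the confirmation span, with columns `t`,
#'   `h_head` and `h_hip`.
#' @param config an [fs_config()].
#' @return a one-row event data frame of kind `confirmed_fall` or
#'   `rejected_candidate`, with the discriminating evidence serialized in the
#'   `evidence` column.
#' @export
confirm_fall <- function(candidate, window, config = fs_config()) {
  config <- as_fs_config(config)
  d <- config$detector
  h <- window$h_head
  ok <- which(!is.na(h))
  if (length(ok) < 3L) {
    return(fs_event("rejected_candidate", candidate$t_start,
                    max(window$t), candidate$source_process, candidate$id,
                    list(reason = "insufficient confirmation data")))
  }
  h_end <- stats::median(h[tail(ok, 5L)])
  hip <- window$h_hip
  hip_ok <- which(!is.na(hip))
  hip_end <- if (length(hip_ok) > 0L) stats::median(hip[tail(hip_ok, 5L)])
             else NA_real_
  below <- h_end < d$near_floor_height
  fb <- which(h < d$near_floor_height)[1L]
  recovered <- !is.na(fb) &&
    any(h[fb:length(h)] > d$recovery_height, na.rm = TRUE)
  drop <- max(h, na.rm = TRUE) - h_end
  drop_ok <- drop >= d$fluctuation_amp
  hs <- runmed_na(h, 3L)
  dh <- diff(hs[!is.na(hs)])
  sgn <- sign(dh[abs(dh) >= 0.005])
  sign_changes <- if (length(sgn) > 1L) sum(diff(sgn) != 0) else 0L
  amp <- diff(range(h, na.rm = TRUE))
  oscillation <- sign_changes >= 2L && amp < d$fluctuation_amp
  hip_low <- is.na(hip_end) || hip_end < d$recovery_height
  confirmed <- below && !recovered && drop_ok && !oscillation && hip_low
  ev <- list(h_end = h_end, hip_end = hip_end,
             near_floor_height = d$near_floor_height,
             recovery_height = d$recovery_height,
             recovered = recovered, net_drop = drop,
             sign_changes = sign_changes, amplitude = amp,
             oscillation = oscillation)
  fs_event(if (confirmed) "confirmed_fall" else "rejected_candidate",
           candidate$t_start, max(window$t), candidate$source_process,
           candidate$id, ev)
}

fs_event <- function(kind, t_start, t_end, source_process = NA_character_,
                     candidate_id = NA_integer_, evidence = list()) {
  data.frame(
    kind = kind, t_start = t_start, t_end = t_end,
    source_process = source_process,
    candidate_id = as.integer(candidate_id),
    evidence = as.character(jsonlite::toJSON(evidence, auto_unbox = TRUE,
                                             digits = 6, na = "null")),
    stringsAsFactors = FALSE)
}

empty_events <- function() {
  data.frame(kind = character(0), t_start = numeric(0), t_end = numeric(0),
             source_process = character(0), candidate_id = integer(0),
             evidence = character(0), stringsAsFactors = FALSE)
}

#' Run the full fall-detection algorithm over a stream
#'
#' Replays the stream frame by frame through the five processes, maintaining
#' a rolling buffer, the per-frame risk level, at most one open fall
#' candidate at a time (a new velocity spike extends the open confirmation
#' window), a recognized-intentional-descent latch that is held until the
#' head recovers above the recovery height, and a post-confirmation
#' suppression until recovery.  Deterministic given `stream` and `config`.
#'
#' @param stream a `skeleton_stream`.
#' @param config an [fs_config()].
#' @return a `detection_events` data frame (possibly zero rows), time
#'   ordered, with columns `kind` (`subject_detected`, `potential_fall`,
#'   `confirmed_fall`, `rejected_candidate`), `t_start`, `t_end`,
#'   `source_process` (`P2`/`P3`/`P4` for the triggering process, `P5` on
#'   resolutions), `candidate_id` and `evidence` (JSON).  The per-frame
#'   process decisions are attached as `attr(, "process_log")`.
#' @export
run_detector <- function(stream, config = fs_config()) {
  config <- as_fs_config(config)
  stopifnot(inherits(stream, "skeleton_stream"))
  n <- n_frames(stream)
  if (n < 2L) {
    ev <- empty_events()
    attr(ev, "process_log") <- rep("no_subject", n)
    class(ev) <- c("detection_events", "data.frame")
    return(ev)
  }
  d <- config$detector
  kin <- compute_kinematics(stream, config)
  factors <- risk_factor_series(stream, config, kin = kin)
  risk <- risk_level_series(factors, config)
  t <- kin$t
  h <- kin$h_head
  # trailing-mean height for descent analysis (jitter suppression)
  hd <- as.numeric(stats::filter(h, rep(1 / 7, 7), sides = 1))
  hip <- kin$h_hip_center

  events <- list()
  log <- rep(NA_character_, n)
  cand <- NULL
  next_id <- 1L
  subject_seen <- FALSE
  suppressed <- FALSE      # after a confirmed fall, until recovery
  intentional <- FALSE     # recognized slow descent, until recovery
  refractory_until <- -Inf

  open_candidate <- function(i, source, evidence) {
    ev <- fs_event("potential_fall", t[i], t[i], source, next_id, evidence)
    events[[length(events) + 1L]] <<- ev
    cand <<- list(id = next_id, t_start = t[i], i_start = i,
                  source_process = source,
                  deadline = t[i] + d$confirm_window)
    next_id <<- next_id + 1L
  }
  resolve_candidate <- function(i, truncated = FALSE) {
    win <- data.frame(t = t[cand$i_start:i], h_head = h[cand$i_start:i],
                      h_hip = hip[cand$i_start:i])
    ev <- confirm_fall(cand, win, config)
    if (truncated) {
      ev$evidence <- as.character(jsonlite::toJSON(
        c(jsonlite::fromJSON(ev$evidence), list(truncated = TRUE)),
        auto_unbox = TRUE, digits = 6, na = "null"))
    }
    events[[length(events) + 1L]] <<- ev
    if (ev$kind == "confirmed_fall") suppressed <<- TRUE
    else refractory_until <<- t[i] + d$refractory_seconds
    cand <<- NULL
  }

  for (i in seq_len(n)) {
    if (!kin$subject[i]) {
      log[i] <- "no_subject"
      next
    }
    if (!subject_seen) {
      subject_seen <- TRUE
      events[[length(events) + 1L]] <-
        fs_event("subject_detected", t[i], t[i], NA_character_, NA_integer_,
                 list(frame = kin$frame[i]))
    }
    if (!is.na(h[i]) && h[i] > d$recovery_height) {
      suppressed <- FALSE
      intentional <- FALSE
    }
    if (!is.null(cand)) {
      log[i] <- "P5"
      if (!is.na(kin$speed[i]) && kin$speed[i] > d$velocity_high) {
        cand$deadline <- t[i] + d$confirm_window
      }
      if (t[i] >= cand$deadline) resolve_candidate(i)
      next
    }
    if (suppressed || t[i] < refractory_until) {
      log[i] <- "suppressed"
      next
    }
    dec <- initial_assessment(kin$speed[i],
                              if (risk$high[i]) "high" else "low", config)
    if (is.null(dec)) {
      log[i] <- "wait"
      next
    }
    if (dec$branch == "to_P5") {
      log[i] <- "P2"
      open_candidate(i, "P2", list(speed = kin$speed[i],
                                   velocity_high = d$velocity_high))
      next
    }
    # the activity recognizer is consulted whenever the risk-adapted or
    # normal test would otherwise alert: a recognized slow descent vetoes
    # (and latches until recovery), a fast one becomes a candidate
    if (dec$branch == "to_P3") {
      log[i] <- "P3"
      if (!intentional &&
          risk_adapted_detection(kin$fine_speed[i], h[i], config)) {
        if (intentional_descent(i, t, hd, config)) {
          intentional <- TRUE
        } else {
          open_candidate(i, "P3",
                         list(fine_speed = kin$fine_speed[i], h_head = h[i],
                              velocity_threshold =
                                d$sensitive_velocity_factor * d$velocity_high,
                              floor_threshold =
                                d$sensitive_floor_factor *
                                  d$near_floor_height))
        }
      }
    } else {
      log[i] <- "P4"
      if (normal_detection(h[i], kin$accel[i], intentional, config)) {
        if (intentional_descent(i, t, hd, config)) {
          intentional <- TRUE
        } else {
          open_candidate(i, "P4",
                         list(h_head = h[i], accel = kin$accel[i],
                              near_floor_height = d$near_floor_height,
                              acceleration_high = d$acceleration_high))
        }
      }
    }
  }
  if (!is.null(cand)) {
    # stream ended with an unresolved candidate: decide on what is available
    resolve_candidate(n, truncated = TRUE)
  }
  out <- if (length(events) > 0L) do.call(rbind, events) else empty_events()
  out <- out[order(out$t_start, out$t_end, method = "radix"), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "process_log") <- log
  class(out) <- c("detection_events", "data.frame")
  out
}

#' @export
print.detection_events <- function(x, ...) {
  cat(sprintf("<detection_events> %d event(s)\n", nrow(x)))
  if (nrow(x) > 0L) {
    print.data.frame(x[, c("kind", "t_start", "t_end", "source_process",
                           "candidate_id")])
  }
  invisible(x)
}

#' Serialize detection events
#'
#' Fixed-format JSON-lines serialization (one event per line); identical
#' inputs produce byte-identical output, which is the package's determinism
#' contract.
#'
#' @param events a `detection_events` data frame.
#' @return character vector, one JSON object per event.
#' @export
serialize_events <- function(events) {
  if (nrow(events) == 0L) return(character(0))
  vapply(seq_len(nrow(events)), function(i) {
    e <- events[i, ]
    sprintf(paste0('{"kind":"%s","t_start":%.6f,"t_end":%.6f,',
                   '"source_process":%s,"candidate_id":%s,"evidence":%s}'),
            e$kind, e$t_start, e$t_end,
            if (is.na(e$source_process)) "null"
            else sprintf('"%s"', e$source_process),
            if (is.na(e$candidate_id)) "null"
            else as.character(e$candidate_id),
            e$evidence)
  }, character(1))
}

#' Write detection events as JSON lines
#' @param events a `detection_events` data frame.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_events_jsonl <- function(events, path) {
  writeLines(serialize_events(events), path)
  invisible(path)
}

#' Summarize detection events as a flat table
#'
#' One row per event without the evidence payload; suitable for a summary
#' CSV export.
#'
#' @param events a `detection_events` data frame.
#' @return a plain data frame.
#' @export
events_summary <- function(events) {
  as.data.frame(events[, c("kind", "t_start", "t_end", "source_process",
                           "candidate_id")])
}
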