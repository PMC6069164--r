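test_that("subject detection requires the key joints", {
  f <- frame_with(list())
  expect_true(detect_subject(f))
  df <- standing_df(1)
  df <- set_joint(df, 1, "head", state = "not_tracked")
  expect_false(detect_subject(get_frame(skeleton_stream(df), 1)))
  f$joints <- list()
  expect_false(detect_subject(f))
})

test_that("the initial assessment routes by velocity then risk", {
  d <- initial_assessment(3.0, "low")
  expect_identical(d$branch, "to_P5")
  expect_true(d$potential_fall)
  expect_identical(initial_assessment(0.3, "high")$branch, "to_P3")
  expect_identical(initial_assessment(0.3, "low")$branch, "to_P4")
  expect_null(initial_assessment(NA_real_, "low"))
})

test_that("the high-risk path is more sensitive than the normal path", {
  # a 1.7 m/s stumble fires under the lowered 0.75 x 2.0 = 1.5 m/s
  # threshold of intensive monitoring ...
  expect_true(risk_adapted_detection(1.7, 1.5))
  # ... but the low-risk path has no velocity test at all
  expect_false(normal_detection(1.5, 0.5, intentional = FALSE))
  # raised near-floor threshold: 0.6 m < 1.25 x 0.5 m
  expect_true(risk_adapted_detection(0.2, 0.6))
  expect_false(normal_detection(0.6, 0.5, intentional = FALSE))
  # standing still at high risk raises nothing
  expect_false(risk_adapted_detection(0.05, 1.65))
})

test_that("the normal path combines near-floor, activity and acceleration", {
  expect_true(normal_detection(0.3, 0.5, intentional = FALSE))
  expect_false(normal_detection(0.3, 0.5, intentional = TRUE))
  expect_true(normal_detection(1.5, 12, intentional = FALSE))
  expect_false(normal_detection(1.5, 12, intentional = TRUE))
  expect_false(normal_detection(1.5, 0.5, intentional = FALSE))
})

confirm_window_df <- function(h, hip = pmax(0.1, h - 0.6)) {
  data.frame(t = (seq_along(h) - 1) / 30, h_head = h, h_hip = hip)
}

test_that("confirmation separates sustained drops from other activities", {
  cand <- list(t_start = 0, source_process = "P2", id = 1L)
  # sustained drop to the floor, resting there: confirmed
  drop <- confirm_window_df(c(seq(1.2, 0.2, length.out = 25), rep(0.2, 21)))
  ev <- confirm_fall(cand, drop)
  expect_identical(ev$kind, "confirmed_fall")

  # walking/running: small up-down fluctuation, no near-floor: rejected
  osc <- confirm_window_df(1.6 + 0.05 * sin(seq(0, 6 * pi, length.out = 46)),
                           hip = rep(0.95, 46))
  evo <- confirm_fall(cand, osc)
  expect_identical(evo$kind, "rejected_candidate")
  expect_true(jsonlite::fromJSON(evo$evidence)$oscillation)

  # drop with recovery above the recovery height: rejected
  rec <- confirm_window_df(c(seq(1.5, 0.4, length.out = 20),
                             seq(0.4, 1.1, length.out = 26)),
                           hip = rep(0.6, 46))
  expect_identical(confirm_fall(cand, rec)$kind, "rejected_candidate")

  # sitting on a chair after a speed spike: final height stays high
  sit <- confirm_window_df(c(seq(1.5, 0.9, length.out = 20), rep(0.9, 26)),
                           hip = rep(0.6, 46))
  expect_identical(confirm_fall(cand, sit)$kind, "rejected_candidate")
})

test_that("a walk-fall-rest stream yields exactly one confirmed fall", {
  for (preset in c("normal", "weak")) {
    sim <- simulate_motion(fall_scenario_script(seed = 21, preset = preset))
    ev <- run_detector(sim$stream)
    expect_equal(sum(ev$kind == "confirmed_fall"), 1L)
    expect_equal(sum(ev$kind == "subject_detected"), 1L)
    # confirmation traces back to a potential fall with the same candidate
    cid <- ev$candidate_id[ev$kind == "confirmed_fall"]
    expect_true(cid %in% ev$candidate_id[ev$kind == "potential_fall"])
  }
})

test_that("slow sitting and lying down raise no confirmed fall", {
  sim <- simulate_motion(slow_lie_script(seed = 22))
  ev <- run_detector(sim$stream)
  expect_equal(sum(ev$kind == "confirmed_fall"), 0L)
})

test_that("a running burst is rejected by the confirmation stage", {
  sim <- simulate_motion(motion_script(
    list(list(activity = "walk", duration = 2.5),
         list(activity = "run", duration = 2),
         list(activity = "walk", duration = 2.5)),
    gait = gait_params("normal"), seed = 11))
  ev <- run_detector(sim$stream)
  expect_gte(sum(ev$kind == "potential_fall"), 1L)
  expect_equal(sum(ev$kind == "confirmed_fall"), 0L)
})

test_that("streams without a detected subject yield no events", {
  df <- standing_df(30)
  for (j in c("head", "shoulder_center", "hip_center")) {
    df[[paste0(j, "_state")]] <- "not_tracked"
  }
  ev <- run_detector(skeleton_stream(df))
  expect_equal(nrow(ev), 0L)
  expect_true(all(attr(ev, "process_log") == "no_subject"))
})

test_that("identical stream and config give byte-identical event logs", {
  sim <- simulate_motion(fall_scenario_script(seed = 23))
  e1 <- serialize_events(run_detector(sim$stream))
  e2 <- serialize_events(run_detector(sim$stream))
  expect_identical(e1, e2)
})

test_that("lowering the velocity threshold never loses potential falls", {
  sim <- simulate_motion(fall_scenario_script(seed = 24))
  counts <- vapply(c(2.5, 2.0, 1.5), function(v) {
    ev <- run_detector(sim$stream, fs_config(detector = list(velocity_high = v)))
    sum(ev$kind == "potential_fall")
  }, numeric(1))
  expect_true(all(diff(counts) >= 0))
})

test_that("all three monitoring branches are exercised on mixed scenarios", {
  logs <- c(
    attr(run_detector(simulate_motion(motion_script(
      list(list(activity = "walk", duration = 3)),
      gait = gait_params("weak"), seed = 25))$stream), "process_log"),
    attr(run_detector(simulate_motion(fall_scenario_script(seed = 26)
    )$stream), "process_log"))
  expect_true(all(c("P3", "P4", "P5") %in% logs))
})
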