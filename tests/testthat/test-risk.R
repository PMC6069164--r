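test_that("step symmetry differences foot separations on the movement axis", {
  f <- frame_with(list())
  expect_equal(step_symmetry(f, f, "axis_x"), 0, ignore_attr = TRUE)

  # separations 0.50 m (previous) and 0.30 m (current), movement along x
  pf <- frame_with(list(foot_l = c(-0.25, -0.86, 2), foot_r = c(0.25, -0.86, 2)))
  cf <- frame_with(list(foot_l = c(-0.15, -0.86, 2), foot_r = c(0.15, -0.86, 2)))
  expect_equal(step_symmetry(pf, cf, "axis_x"), 0.2, ignore_attr = TRUE)
  # sign preserved when the separation grows
  expect_equal(step_symmetry(cf, pf, "axis_x"), -0.2, ignore_attr = TRUE)

  # movement along z: z-separations equal, differing x-separations ignored
  pf2 <- frame_with(list(foot_l = c(-0.25, -0.86, 1.8), foot_r = c(0.25, -0.86, 2.2)))
  cf2 <- frame_with(list(foot_l = c(-0.1, -0.86, 1.8), foot_r = c(0.1, -0.86, 2.2)))
  expect_equal(step_symmetry(pf2, cf2, "axis_z"), 0, ignore_attr = TRUE)

  # untracked foot: unavailable
  df <- standing_df(1)
  df <- set_joint(df, 1, "foot_l", state = "not_tracked")
  fu <- get_frame(skeleton_stream(df), 1)
  expect_true(is.na(step_symmetry(fu, f, "axis_x")))
})

test_that("trunk sway averages the lateral torso offset over both frames", {
  f <- frame_with(list())
  expect_equal(trunk_sway(f, f, "axis_z"), 0, ignore_attr = TRUE)

  # lateral offsets 0.10 and 0.14 m in consecutive frames -> 0.12 m
  pf <- frame_with(list(torso = c(0.10, 0.24, 2)))
  cf <- frame_with(list(torso = c(0.14, 0.24, 2)))
  expect_equal(trunk_sway(pf, cf, "axis_z"), 0.12, ignore_attr = TRUE)

  # mirror image negates
  pfm <- frame_with(list(torso = c(-0.10, 0.24, 2)))
  cfm <- frame_with(list(torso = c(-0.14, 0.24, 2)))
  expect_equal(trunk_sway(pfm, cfm, "axis_z"), -0.12, ignore_attr = TRUE)
})

test_that("arm spread is the change in mean torso-to-arm distance", {
  f <- frame_with(list())
  expect_equal(spread_arm(f, f, "axis_z"), 0, ignore_attr = TRUE)

  # mean arm distance 0.25 m -> 0.45 m between frames
  pf <- frame_with(list(hand_l = c(-0.25, -0.01, 2), hand_r = c(0.25, -0.01, 2)))
  cf <- frame_with(list(hand_l = c(-0.45, -0.01, 2), hand_r = c(0.45, -0.01, 2)))
  expect_equal(spread_arm(pf, cf, "axis_z"), 0.2, ignore_attr = TRUE)
  # closing arms give a negative value
  expect_equal(spread_arm(cf, pf, "axis_z"), -0.2, ignore_attr = TRUE)
})

test_that("risk factors are invariant under rigid translation", {
  set.seed(104)
  for (k in 1:50) {
    off <- stats::runif(3, -0.5, 0.5)
    off[2] <- max(off[2], -0.3)
    mk <- function(shift) {
      df <- standing_df(2)
      df <- set_joint(df, 1, "torso", x = 0.07)
      df <- set_joint(df, 2, "foot_r", z = 2.3)
      df <- set_joint(df, 2, "hand_r", x = 0.4)
      for (j in fs_joints()) {
        df[[paste0(j, "_x")]] <- df[[paste0(j, "_x")]] + shift[1]
        df[[paste0(j, "_y")]] <- df[[paste0(j, "_y")]] + shift[2]
        df[[paste0(j, "_z")]] <- df[[paste0(j, "_z")]] + shift[3]
      }
      s <- skeleton_stream(df)
      list(get_frame(s, 1), get_frame(s, 2))
    }
    base <- mk(c(0, 0, 0))
    shifted <- mk(off)
    for (op in list(step_symmetry, trunk_sway, spread_arm)) {
      expect_equal(op(shifted[[1]], shifted[[2]], "axis_z"),
                   op(base[[1]], base[[2]], "axis_z"),
                   tolerance = 1e-9, ignore_attr = TRUE)
    }
  }
})

test_that("risk assessment applies the OR rule over windowed aggregates", {
  w <- data.frame(step_symmetry = rep(0.02, 80), trunk_sway = rep(0.01, 80),
                  spread_arm = rep(0.02, 80))
  expect_identical(assess_risk(w)$level, "low")
  w2 <- w
  w2$trunk_sway <- rep(0.08, 80)   # one factor over threshold suffices
  a2 <- assess_risk(w2)
  expect_identical(a2$level, "high")
  expect_true(a2$exceeded[["trunk_sway"]])

  # monotone: raising any single factor never flips high back to low
  w3 <- w2
  w3$step_symmetry <- w3$step_symmetry * 50
  expect_identical(assess_risk(w3)$level, "high")

  # short or empty windows are insufficient, reported as such
  expect_true(assess_risk(w[1:10, ])$insufficient)
  expect_true(assess_risk(w[0, ])$insufficient)
})

test_that("gait presets separate into the intended risk levels", {
  n_low <- n_high <- 0L
  asym <- c()
  for (seed in 1:20) {
    rn <- assess_stream_risk(simulate_motion(motion_script(
      list(list(activity = "walk", duration = 4)),
      gait = gait_params("normal"), seed = seed))$stream)
    rw <- assess_stream_risk(simulate_motion(motion_script(
      list(list(activity = "walk", duration = 4)),
      gait = gait_params("weak"), seed = seed + 500))$stream)
    n_low <- n_low + (rn$level == "low")
    n_high <- n_high + (rw$level == "high")
    asym <- c(asym, rw$aggregates[["step_symmetry"]])
  }
  expect_gte(n_low, 19L)
  expect_gte(n_high, 19L)
  # the estimator recovers the configured 0.2 m step-length asymmetry
  expect_lt(abs(mean(asym) - 0.2) / 0.2, 0.3)
})
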