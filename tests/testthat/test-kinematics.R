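test_that("joint height equals the point-to-plane distance", {
  expect_equal(joint_height(c(0, 1.5, 2), floor_plane(0, 1, 0, 0)), 1.5)
  # camera 0.91 m above the floor (3-foot placement): D shifts the height
  expect_equal(joint_height(c(0, 0.59, 2), floor_plane(0, 1, 0, 0.91)), 1.5)
  # plane vector scaling is normalized away
  expect_equal(joint_height(c(0, 1.5, 2), c(0, 2, 0, 0)), 1.5)
  # a joint on the plane has height zero
  expect_equal(joint_height(c(0, -0.91, 2), floor_plane(0, 1, 0, 0.91)), 0)
  expect_error(joint_height(c(0, 1, 2), c(0, 0, 0, 1)), "degenerate")
  expect_true(is.na(joint_height(joint_position(0, 0, 0, "not_tracked"),
                                 floor_plane(0, 1, 0, 0))))
})

test_that("joint height matches the projection oracle on random inputs", {
  set.seed(101)
  for (k in 1:1000) {
    p <- stats::runif(3, -3, 3)
    plane <- c(stats::runif(3, -1, 1), stats::runif(1, 0, 2))
    if (sum(plane[1:3]^2) < 1e-6) next
    expect_equal(joint_height(p, plane), plane_distance_oracle(p, plane),
                 tolerance = 1e-9)
  }
})

test_that("joint height is invariant to plane scaling and in-plane shifts", {
  set.seed(102)
  for (k in 1:200) {
    p <- stats::runif(3, -2, 2)
    plane <- c(stats::runif(3, -1, 1), stats::runif(1, 0, 2))
    if (sum(plane[1:3]^2) < 1e-6) next
    s <- stats::runif(1, 0.1, 10)
    expect_equal(joint_height(p, plane * s), joint_height(p, plane),
                 tolerance = 1e-9)
    # translate the point parallel to the plane
    nvec <- plane[1:3]
    v <- stats::runif(3, -1, 1)
    v <- v - sum(v * nvec) / sum(nvec^2) * nvec
    expect_equal(joint_height(p + v, plane), joint_height(p, plane),
                 tolerance = 1e-8)
  }
})

test_that("movement direction classifies axis, irregular and stationary", {
  expect_identical(movement_direction(c(0, 0, 0), c(0.10, 0, 0)), "axis_x")
  expect_identical(movement_direction(c(0, 0, 0), c(0, 0, 0)), "stationary")
  expect_identical(movement_direction(c(1, 1, 1), c(1, 1, 1.2)), "axis_z")
  # dominance 0.686 < 0.8: off-axis
  expect_identical(movement_direction(c(0, 0, 0), c(0.03, 0.04, 0.03)),
                   "irregular")
  # exactly at the dominance boundary: ties classify as axis-aligned
  boundary <- 0.04 / sqrt(0.03^2 + 0.04^2 + 0)
  expect_identical(movement_direction(c(0, 0, 0), c(0.03, -0.04, 0),
                                      dominance = boundary), "axis_y")
  expect_identical(movement_direction(c(0, 0, 0), c(0.03, -0.04, 0),
                                      dominance = 0.81), "irregular")
})

test_that("irregular distance is the in-plane Euclidean length", {
  expect_equal(irregular_distance(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(irregular_distance(c(0, 0, 0), c(3, 4, 0)), 5)
  set.seed(103)
  for (k in 1:1000) {
    a <- stats::runif(3, -5, 5)
    b <- stats::runif(3, -5, 5)
    # independent oracle: modulus of the complex in-plane displacement
    oracle <- Mod(complex(real = b[1] - a[1], imaginary = b[2] - a[2]))
    expect_equal(irregular_distance(a, b), oracle, tolerance = 1e-12)
    expect_equal(irregular_distance(b, a), irregular_distance(a, b))
    # never less than the displacement along either in-plane axis
    expect_gte(irregular_distance(a, b) + 1e-15, abs(b[1] - a[1]))
    expect_gte(irregular_distance(a, b) + 1e-15, abs(b[2] - a[2]))
  }
})

test_that("instantaneous speed follows the skip-one arithmetic", {
  expect_equal(instantaneous_speed(1, 1, 0.2, 0.1), 0)
  # 0.10 m over the 1/15 s skip-one interval
  expect_equal(instantaneous_speed(0.10, 0, 1 / 15, 0), 1.5)
  expect_error(instantaneous_speed(1, 0, 0.1, 0.1), "t_c")
})

test_that("kinematic samples derive heights, direction and speed", {
  cfg <- fs_config(joints = list(tracking = "head"))
  f1 <- get_frame(standing_stream(2), 1)
  f2 <- get_frame(standing_stream(2), 2)
  f2$t <- 1 / 15
  ks <- kinematic_sample(list(f1, f2), config = cfg)
  expect_identical(ks$direction, "stationary")
  expect_equal(ks$speed, 0)
  expect_equal(unname(ks$heights[["head"]]), 1.65, tolerance = 1e-9)

  # simulated fall pair: head height 1.5 -> 1.3 over 1/15 s gives 3 m/s
  df <- standing_df(2, dt = 1 / 15)
  df <- set_joint(df, 1, "head", y = 1.5 - 0.91)
  df <- set_joint(df, 2, "head", y = 1.3 - 0.91)
  s <- skeleton_stream(df)
  ks2 <- kinematic_sample(list(get_frame(s, 1), get_frame(s, 2)),
                          config = cfg)
  expect_equal(ks2$speed, 3.0, tolerance = 1e-9)
  expect_identical(ks2$direction, "axis_y")

  # one frame is not enough
  expect_null(kinematic_sample(list(f1), config = cfg))
  # untracked key joints in both frames: unavailable sample
  df3 <- standing_df(2)
  df3 <- set_joint(df3, 1, "head", state = "not_tracked")
  df3 <- set_joint(df3, 2, "head", state = "not_tracked")
  s3 <- skeleton_stream(df3)
  expect_null(kinematic_sample(list(get_frame(s3, 1), get_frame(s3, 2)),
                               config = cfg))
})

test_that("a rigid horizontal offset leaves heights and speeds unchanged", {
  sim <- simulate_motion(motion_script(
    list(list(activity = "walk", duration = 2)),
    gait = gait_params("normal"), seed = 9))
  s1 <- sim$stream
  s2 <- s1
  for (j in fs_joints()) {
    s2$frames[[paste0(j, "_x")]] <- s2$frames[[paste0(j, "_x")]] + 0.7
    s2$frames[[paste0(j, "_z")]] <- s2$frames[[paste0(j, "_z")]] + 1.1
  }
  k1 <- compute_kinematics(s1)
  k2 <- compute_kinematics(s2)
  expect_equal(k2$h_head, k1$h_head, tolerance = 1e-9)
  expect_equal(k2$speed, k1$speed, tolerance = 1e-9)
  expect_equal(k2$accel, k1$accel, tolerance = 1e-8)
})
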