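make_straight_trial <- function(A = 300, T = 1.0, rate = 100,
                                start = c(250, 0, -250)) {
  minimum_jerk_path(start, start + c(A, 0, 0), T, sample_rate = rate)
}

test_that("tangential velocity reproduces constant-speed and stationary motion", {
  t <- seq(0, 1, by = 0.01)
  pos <- cbind(100 * t, 0 * t, 0 * t)   # 100 mm/s along x
  v <- tangential_velocity(tip_trajectory(t, pos))
  expect_equal(v, rep(100, length(t)), tolerance = 1e-9)
  v0 <- tangential_velocity(tip_trajectory(t, matrix(5, length(t), 3)))
  expect_equal(v0, rep(0, length(t)))
  expect_error(tangential_velocity(tip_trajectory(c(0, 0.01, 0.5), pos[1:3, ])),
               "not uniformly sampled")
})

test_that("minimum-jerk reach hits the closed-form peak speed", {
  traj <- make_straight_trial()
  v <- tangential_velocity(traj)
  expect_equal(max(v), min_jerk_peak_speed(300, 1.0), tolerance = 0.01)
})

test_that("bounds detection matches a brute-force predicate scan", {
  traj <- make_straight_trial()
  v <- tangential_velocity(traj)
  start <- c(250, 0, -250); target <- start + c(300, 0, 0)
  b <- detect_bounds(traj, v, start, target)
  oracle <- scan_bounds_oracle(traj$position, v, start, target)
  expect_identical(b$start_index, oracle$start_index)
  expect_identical(b$end_index, oracle$end_index)
  expect_equal(b$movement_time,
               traj$time[b$end_index] - traj$time[b$start_index])
  # idempotence: re-detection on the cropped trajectory spans the crop
  crop <- tip_trajectory(traj$time[b$start_index:b$end_index],
                         traj$position[b$start_index:b$end_index, ])
  b2 <- detect_bounds(crop, v[b$start_index:b$end_index], start, target)
  expect_identical(b2$start_index, 1L)
  expect_identical(b2$end_index, b$end_index - b$start_index + 1L)
})

test_that("bounds detection failures name the missing bound", {
  t <- seq(0, 1, by = 0.01)
  slow <- tip_trajectory(t, cbind(10 * t, 0 * t, 0 * t))  # never above 25 mm/s
  v <- tangential_velocity(slow)
  expect_error(detect_bounds(slow, v, c(0, 0, 0), c(300, 0, 0)),
               "no movement start")
  short <- make_straight_trial(A = 280)   # stops 20 mm short of the target
  vs <- tangential_velocity(short)
  expect_error(detect_bounds(short, vs, c(250, 0, -250), c(550, 0, -250)),
               "no movement end")
})

test_that("phase split is symmetric for minimum jerk and degenerate at edges", {
  traj <- make_straight_trial()
  v <- tangential_velocity(traj)
  # over the nominal (symmetric) movement window the split at the velocity
  # peak differs by at most one 10 ms sample
  b <- list(start_index = attr(traj, "move_start_index"),
            end_index = attr(traj, "move_end_index"))
  b$movement_time <- traj$time[b$end_index] - traj$time[b$start_index]
  ph <- phase_times(traj, v, b)
  expect_lt(abs(ph$acceleration_time - ph$deceleration_time), 0.0101)
  expect_equal(ph$acceleration_time + ph$deceleration_time, b$movement_time,
               tolerance = 1e-12)
  # detected bounds are asymmetric by construction of the detection rule
  # (start requires leaving the 10 mm start radius; the end triggers at the
  # velocity crossing already well inside the target radius), but the two
  # phases still partition the detected movement time exactly
  bd <- detect_bounds(traj, v, c(250, 0, -250), c(550, 0, -250))
  phd <- phase_times(traj, v, bd)
  expect_equal(phd$acceleration_time + phd$deceleration_time,
               bd$movement_time, tolerance = 1e-12)
  # monotonically decreasing velocity -> acceleration time 0
  vmono <- rev(seq_along(traj$time))
  ph2 <- phase_times(traj, vmono, b)
  expect_equal(ph2$acceleration_time, 0)
  # peak at the final in-bounds sample -> deceleration time 0
  vend <- seq_along(traj$time)
  ph3 <- phase_times(traj, vend, b)
  expect_equal(ph3$deceleration_time, 0)
})

test_that("curvature is zero on a straight path and recovers a constructed bulge", {
  traj <- make_straight_trial()
  v <- tangential_velocity(traj)
  start <- c(250, 0, -250); target <- c(550, 0, -250)
  b <- detect_bounds(traj, v, start, target)
  expect_lt(path_curvature(traj, b, start, target, "horizontal"), 1e-9)
  expect_lt(path_curvature(traj, b, start, target, "vertical"), 1e-9)
  # path bulging 15 mm in +y at midpoint, flat in z
  pos <- traj$position
  s <- (pos[, 1] - start[1]) / 300
  pos[, 2] <- pos[, 2] + 15 * sin(pi * pmin(pmax(s, 0), 1))
  bul <- tip_trajectory(traj$time, pos)
  expect_equal(path_curvature(bul, b, start, target, "horizontal"), 15,
               tolerance = 1e-6)
  expect_lt(path_curvature(bul, b, start, target, "vertical"), 1e-9)
  expect_error(path_curvature(traj, b, start, start, "vertical"), "coincide")
})

test_that("vertical curvature of a circular arc equals the sagitta", {
  # arc in the x-z plane: chord 300 mm, radius 300 mm -> sagitta
  # 300 - sqrt(300^2 - 150^2) = 40.19 mm
  start <- c(0, 0, 0); target <- c(300, 0, 0)
  theta <- seq(-pi / 6, pi / 6, length.out = 101)
  center <- c(150, 0, -300 * cos(pi / 6))
  pos <- cbind(center[1] + 300 * sin(theta), 0,
               center[3] + 300 * cos(theta))
  traj <- tip_trajectory(seq_along(theta) / 100, pos)
  b <- list(start_index = 1L, end_index = 101L, movement_time = 1)
  sagitta <- 300 - sqrt(300^2 - 150^2)
  expect_equal(path_curvature(traj, b, start, target, "vertical"), sagitta,
               tolerance = 0.5 / sagitta)
  # curvature is invariant under rigid translation of path and chord
  shift <- c(-120, 40, 300)
  traj2 <- tip_trajectory(traj$time, sweep(pos, 2, -shift))
  expect_equal(path_curvature(traj2, b, start + shift, target + shift,
                              "vertical"),
               path_curvature(traj, b, start, target, "vertical"),
               tolerance = 1e-12)
})

test_that("accuracy errors: arithmetic cases and the isotropic-noise closed form", {
  target <- c(10, 20, 30)
  on_target <- matrix(target, 4, 3, byrow = TRUE)
  res <- accuracy_errors(on_target, target)
  expect_equal(res$absolute_error, 0)
  expect_equal(res$variable_error, 0)
  two <- rbind(target + c(3, 0, 0), target + c(0, 0, 5))
  res2 <- accuracy_errors(two, target)
  expect_equal(res2$absolute_error, 4)
  expect_equal(res2$variable_error, sqrt(2))
  expect_error(accuracy_errors(matrix(0, 1, 3), target), "at least 2")
  # isotropic 3-D noise, sigma = 2 mm per axis: mean distance is the
  # chi-3 mean, 2 * sigma * sqrt(2/pi)
  set.seed(12)
  pts <- matrix(rnorm(3000, sd = 2), 1000, 3) +
    matrix(target, 1000, 3, byrow = TRUE)
  res3 <- accuracy_errors(pts, target)
  expect_equal(res3$absolute_error, 2 * 2 * sqrt(2 / pi), tolerance = 0.05)
})

test_that("time normalization is linear, exact at the endpoint, and identity on aligned grids", {
  traj <- make_straight_trial()
  v <- tangential_velocity(traj)
  b <- detect_bounds(traj, v, c(250, 0, -250), c(550, 0, -250))
  const <- rep(7, length(traj$time))
  expect_equal(time_normalize(const, traj$time, b), rep(7, 100))
  # linear ramp from a to b over the movement: point k = a + (b - a) k/100
  t0 <- traj$time[b$start_index]; mt <- b$movement_time
  ramp <- 2 + 5 * (traj$time - t0) / mt
  out <- time_normalize(ramp, traj$time, b)
  expect_equal(out, 2 + 5 * (1:100) / 100, tolerance = 1e-12)
  expect_equal(out[100], ramp[b$end_index])
  # identity resampling: input already on the normalized grid (start sample
  # plus 100 equal steps) comes back unchanged
  t101 <- seq(0, 1, length.out = 101)
  series <- sin(seq(0, 3, length.out = 101))
  b101 <- list(start_index = 1L, end_index = 101L, movement_time = 1)
  expect_equal(time_normalize(series, t101, b101), series[2:101],
               tolerance = 1e-9)
  # matrix input normalizes each column
  m <- cbind(ramp, const)
  outm <- time_normalize(m, traj$time, b)
  expect_identical(dim(outm), c(100L, 2L))
  expect_equal(outm[, 2], rep(7, 100), ignore_attr = TRUE)
  expect_error(time_normalize(const, traj$time,
                              list(start_index = 5L, end_index = 5L)),
               "fewer than 2")
})
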