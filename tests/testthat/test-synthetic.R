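test_that("minimum-jerk path honors endpoints, symmetry and the peak closed form", {
  start <- c(250, 0, -250); target <- c(550, 0, -250)
  traj <- minimum_jerk_path(start, target, 1.0, sample_rate = 100)
  i0 <- attr(traj, "move_start_index"); i1 <- attr(traj, "move_end_index")
  expect_equal(unname(traj$position[1, ]), start)
  expect_equal(unname(traj$position[nrow(traj$position), ]), target)
  # midpoint of the motion lies exactly halfway
  mid <- traj$position[(i0 + i1) / 2 + 0.5, ]
  expect_equal(unname(mid), (start + target) / 2, tolerance = 1e-12)
  v <- tangential_velocity(traj)
  expect_equal(max(v), 1.875 * 300 / 1.0, tolerance = 0.01)
  expect_error(minimum_jerk_path(start, start, 1.0), "coincide")
  expect_error(minimum_jerk_path(start, target, -1), "positive")
})

test_that("inverse kinematics reproduces the tip path and is deterministic", {
  cond <- condition_spec(0, FALSE)
  geom <- default_geometry(0)
  path <- minimum_jerk_path(cond$start_point, cond$target_point,
                            cond$movement_time, cond$sample_rate)
  q <- reference_joint_trajectory(path, geom, default_initial_config_test())
  tips <- fk_trajectory(q, geom)
  expect_lt(max(sqrt(rowSums((tips - path$position)^2))), 0.01)
  q2 <- reference_joint_trajectory(path, geom, default_initial_config_test())
  expect_identical(q, q2)
})

test_that("unreachable targets raise a reachability error naming the sample", {
  geom <- default_geometry(0)   # total reach 700 mm
  path <- minimum_jerk_path(c(250, 0, -250), c(800, 0, -250), 1.0)
  expect_error(reference_joint_trajectory(path, geom,
                                          default_initial_config_test()),
               "unreachable tip sample")
})

test_that("condition geometry follows the displacement rule", {
  for (rod in c(0, 100, 200, 300)) {
    fixed <- condition_spec(rod, FALSE)
    disp <- condition_spec(rod, TRUE)
    # 300 mm start-target separation in every condition
    expect_equal(sqrt(sum((fixed$target_point - fixed$start_point)^2)), 300)
    expect_equal(sqrt(sum((disp$target_point - disp$start_point)^2)), 300)
    # displaced: both points move away from the shoulder by the rod length
    expect_equal(disp$start_point - fixed$start_point, c(rod, 0, 0))
  }
  design <- study_design()
  expect_length(design, 8L)
  expect_equal(sum(vapply(design, `[[`, logical(1), "displaced")), 4L)
  expect_setequal(vapply(design, `[[`, numeric(1), "rod_length"),
                  c(0, 100, 200, 300))
})

test_that("non-displaced joint excursions shrink with rod length; displaced do not", {
  path_len <- function(rod, displaced) {
    ref <- condition_reference(condition_spec(rod, displaced))
    sum(abs(diff(ref$angles)))
  }
  fixed <- vapply(c(0, 100, 200, 300), path_len, numeric(1),
                  displaced = FALSE)
  expect_true(all(diff(fixed) < 0))
  # displaced conditions keep the 300 mm tip amplitude for every rod length
  for (rod in c(0, 300)) {
    ref <- condition_reference(condition_spec(rod, TRUE))
    amp <- sqrt(sum((ref$tip[ref$move_end_index, ] -
                       ref$tip[ref$move_start_index, ])^2))
    expect_equal(amp, 300, tolerance = 1e-9)
  }
})

test_that("zero-noise ensembles reproduce the reference exactly", {
  cond <- condition_spec(0, FALSE, n_trials = 3)
  ref <- condition_reference(cond)
  ens <- generate_condition_dataset(cond, model = variability_model(0, 0, seed = 1),
                                    reference = ref)
  for (j in 1:3) {
    expect_equal(ens$angles[, , j], ref$angles, ignore_attr = TRUE)
    # tips reproduce the nominal minimum-jerk path to the IK tolerance
    expect_lt(max(abs(ens$tips[, , j] - ref$tip)), 0.01)
  }
  u <- ensemble_ucm(ens)
  expect_equal(u$gev, 0)
  expect_equal(u$ngev, 0)
})

test_that("ensembles are reproducible by seed and differ across seeds", {
  cond <- condition_spec(100, TRUE, n_trials = 4)
  ref <- condition_reference(cond)
  e1 <- generate_condition_dataset(cond, model = variability_model(seed = 7),
                                   reference = ref)
  e2 <- generate_condition_dataset(cond, model = variability_model(seed = 7),
                                   reference = ref)
  e3 <- generate_condition_dataset(cond, model = variability_model(seed = 8),
                                   reference = ref)
  expect_identical(e1$angles, e2$angles)
  expect_false(identical(e1$angles, e3$angles))
})

test_that("injected subspace variances are recovered at the injection instant", {
  cond <- condition_spec(0, FALSE, n_trials = 500)
  ref <- condition_reference(cond)
  model <- variability_model(sigma_gev = 2 * pi / 180,
                             sigma_ngev = 0.5 * pi / 180, seed = 33)
  ens <- generate_condition_dataset(cond, model = model, reference = ref)
  u <- ensemble_ucm(ens)
  expect_equal(u$gev, model$sigma_gev^2, tolerance = 0.15)
  expect_equal(u$ngev, model$sigma_ngev^2, tolerance = 0.15)
  expect_equal(u$v_ratio, 16, tolerance = 0.3)
  expect_true(u$v_ratio_log > 0)
  # the trace-formula estimate agrees with the explicit projection oracle
  configs <- t(ens$angles[ref$move_end_index, , ])
  b <- subspace_bases(compute_jacobian(colMeans(configs), ens$geometry))
  uo <- ucm_decompose_oracle(configs, b)
  expect_equal(u$gev, uo$gev, tolerance = 1e-10)
  expect_equal(u$ngev, uo$ngev, tolerance = 1e-10)
})
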