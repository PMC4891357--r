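# Independent oracles and shared fixtures for the test suite.

test_geometry <- function(rod = 0) arm_geometry(300, 250, 80, 70, rod)

# Closed-form planar 2-link reduction: only shoulder_elevation (q2, about y)
# and elbow_flexion (q4, about -y) nonzero. Link 1 = upper arm; link 2 =
# forearm + hand + finger + rod. Hand-coded trigonometric formula, kept
# independent of the package's rotation-matrix chain.
planar_two_link_position <- function(q2, q4, geometry) {
  L1 <- geometry$upper_arm_length
  L2 <- geometry$forearm_length + geometry$hand_length +
    geometry$finger_length + geometry$rod_length
  a2 <- q2 - q4
  c(L1 * cos(q2) + L2 * cos(a2), 0, -(L1 * sin(q2) + L2 * sin(a2)))
}

# Analytic Jacobian of the planar reduction w.r.t. (q2, q4): a 3x2 matrix.
planar_two_link_jacobian <- function(q2, q4, geometry) {
  L1 <- geometry$upper_arm_length
  L2 <- geometry$forearm_length + geometry$hand_length +
    geometry$finger_length + geometry$rod_length
  a2 <- q2 - q4
  matrix(c(
    -L1 * sin(q2) - L2 * sin(a2),  L2 * sin(a2),
    0,                             0,
    -L1 * cos(q2) - L2 * cos(a2),  L2 * cos(a2)
  ), nrow = 3, byrow = TRUE)
}

# A non-degenerate reference posture used across tests.
bent_posture <- function() {
  c(0.15, 0.9, 0.1, 1.2, 0.2, 0.05, 0.3, 0.02, 0.25)
}

random_posture <- function() {
  bent_posture() + stats::runif(9, -0.3, 0.3)
}

# Random symmetric positive-semidefinite 9x9 matrix.
random_psd <- function(scale = 1e-4) {
  A <- matrix(stats::rnorm(81), 9, 9)
  crossprod(A) * scale
}

# Minimum-jerk closed forms for a straight reach of amplitude A in time T.
min_jerk_peak_speed <- function(A, T) 1.875 * A / T

# Brute-force per-sample scan of the two bounds-detection predicates, used as
# the oracle for detect_bounds.
scan_bounds_oracle <- function(pos, vel, start_point, target_point,
                               threshold = 25, radius = 10) {
  n <- nrow(pos)
  start_index <- NA_integer_
  for (i in seq_len(n)) {
    if (vel[i] > threshold &&
        sqrt(sum((pos[i, ] - start_point)^2)) > radius) {
      start_index <- i
      break
    }
  }
  end_index <- NA_integer_
  if (!is.na(start_index) && start_index < n) {
    for (i in (start_index + 1L):n) {
      if (vel[i] < threshold &&
          sqrt(sum((pos[i, ] - target_point)^2)) < radius) {
        end_index <- i
        break
      }
    }
  }
  list(start_index = start_index, end_index = end_index)
}

# Seed posture used for inverse-kinematics tests (matches the package default).
default_initial_config_test <- function() {
  c(0, 1.35, 0, 1.75, 0, 0, 0.25, 0, 0.25)
}
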