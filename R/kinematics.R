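#' Tip trajectory container
#'
#' A 3-D end-effector tip trajectory sampled at (by default) 100 Hz.
#'
#' @param time numeric vector of sample times, s, strictly increasing
#' @param position numeric matrix (n x 3) of tip positions, mm
#' @return object of class `tip_trajectory` (list with `time`, `position`)
#' @export
tip_trajectory <- function(time, position) {
  position <- as.matrix(position)
  if (length(time) < 3L)
    stop("trajectory needs at least 3 samples", call. = FALSE)
  if (ncol(position) != 3L || nrow(position) != length(time))
    stop("position must be an n x 3 matrix matching time", call. = FALSE)
  if (any(diff(time) <= 0))
    stop("time must be strictly increasing", call. = FALSE)
  if (!all(is.finite(time)) || !all(is.finite(position)))
    stop("trajectory contains non-finite values", call. = FALSE)
  colnames(position) <- c("x", "y", "z")
  structure(list(time = as.numeric(time), position = position),
            class = "tip_trajectory")
}

check_uniform <- function(time) {
  dt <- diff(time)
  if (max(dt) - min(dt) > 1e-6 * stats::median(dt))
    stop("trajectory is not uniformly sampled", call. = FALSE)
  stats::median(dt)
}

#' Tangential velocity of a tip trajectory
#'
#' The speed along the 3-D path: the square root of the sum of the squared
#' derivatives of the positional coordinates. Derivatives use central
#' differences in the interior and one-sided differences at the two ends; no
#' smoothing is applied.
#'
#' @param traj a [tip_trajectory()]
#' @return numeric vector of speeds, mm/s, one per sample
#' @export
tangential_velocity <- function(traj) {
  stopifnot(inherits(traj, "tip_trajectory"))
  check_uniform(traj$time)
  p <- traj$position
  t <- traj$time
  n <- nrow(p)
  d <- matrix(NA_real_, n, 3L)
  d[1, ] <- (p[2, ] - p[1, ]) / (t[2] - t[1])
  d[n, ] <- (p[n, ] - p[n - 1, ]) / (t[n] - t[n - 1])
  if (n > 2L) {
    idx <- 2:(n - 1)
    d[idx, ] <- (p[idx + 1, , drop = FALSE] - p[idx - 1, , drop = FALSE]) /
      (t[idx + 1] - t[idx - 1])
  }
  sqrt(rowSums(d^2))
}

#' Detect movement start and end
#'
#' Movement start: the first sample where tangential velocity rises above
#' `speed_threshold` (25 mm/s) while the tip is outside `radius` (10 mm) of
#' the start point. Movement end: the first subsequent sample where velocity
#' falls below the threshold while the tip is within `radius` of the target.
#' Both predicates are strict inequalities and must hold simultaneously.
#'
#' @param traj a [tip_trajectory()]
#' @param velocity tangential velocity, mm/s (from [tangential_velocity()])
#' @param start_point,target_point 3-D points, mm
#' @param speed_threshold velocity threshold, mm/s
#' @param radius start/target radius, mm
#' @return list with `start_index`, `end_index`, `movement_time` (s)
#' @export
detect_bounds <- function(traj, velocity, start_point, target_point,
                          speed_threshold = 25, radius = 10) {
  stopifnot(inherits(traj, "tip_trajectory"), length(velocity) == nrow(traj$position))
  d_start <- sqrt(colSums((t(traj$position) - start_point)^2))
  d_target <- sqrt(colSums((t(traj$position) - target_point)^2))
  started <- velocity > speed_threshold & d_start > radius
  start_index <- which(started)[1L]
  if (is.na(start_index))
    stop("bounds detection failed: no movement start found ",
         "(velocity never exceeded threshold outside the start radius)",
         call. = FALSE)
  ended <- velocity < speed_threshold & d_target < radius
  ended[seq_len(start_index)] <- FALSE
  end_index <- which(ended)[1L]
  if (is.na(end_index))
    stop("bounds detection failed: no movement end found ",
         "(velocity never dropped below threshold inside the target radius)",
         call. = FALSE)
  list(start_index = start_index, end_index = end_index,
       movement_time = traj$time[end_index] - traj$time[start_index])
}

#' Acceleration and deceleration times
#'
#' Splits the movement at the instant of maximum tangential velocity within
#' the detected bounds (earliest maximum on ties): acceleration time runs from
#' movement start to the velocity peak, deceleration time from the peak to
#' movement end.
#'
#' @param traj a [tip_trajectory()]
#' @param velocity tangential velocity, mm/s
#' @param bounds from [detect_bounds()]
#' @return list with `acceleration_time`, `deceleration_time` (s),
#'   `peak_velocity` (mm/s), `peak_index`
#' @export
phase_times <- function(traj, velocity, bounds) {
  idx <- bounds$start_index:bounds$end_index
  v <- velocity[idx]
  peak_local <- which.max(v)  # earliest maximum on ties
  peak_index <- idx[peak_local]
  list(
    acceleration_time = traj$time[peak_index] - traj$time[bounds$start_index],
    deceleration_time = traj$time[bounds$end_index] - traj$time[peak_index],
    peak_velocity = velocity[peak_index],
    peak_index = peak_index
  )
}

#' Path curvature relative to the start-target chord
#'
#' Maximum deviation of the in-bounds tip path from the straight line between
#' start point and target, after projecting both path and chord onto the
#' horizontal (transversal, lab x-y) or vertical (sagittal, lab x-z) plane.
#' Unsigned.
#'
#' @inheritParams phase_times
#' @param start_point,target_point 3-D points, mm
#' @param plane `"horizontal"` (x-y) or `"vertical"` (x-z)
#' @return maximum perpendicular deviation, mm
#' @export
path_curvature <- function(traj, bounds, start_point, target_point,
                           plane = c("horizontal", "vertical")) {
  plane <- match.arg(plane)
  if (isTRUE(all.equal(start_point, target_point)))
    stop("start_point and target_point coincide", call. = FALSE)
  keep <- if (plane == "horizontal") c(1L, 2L) else c(1L, 3L)
  p <- traj$position[bounds$start_index:bounds$end_index, keep, drop = FALSE]
  a <- start_point[keep]
  b <- target_point[keep]
  chord <- b - a
  len <- sqrt(sum(chord^2))
  if (len < .Machine$double.eps)
    stop("start and target coincide in the ", plane, " plane", call. = FALSE)
  u <- chord / len
  rel <- sweep(p, 2L, a)
  # perpendicular distance to the (infinite) chord line in 2-D
  perp <- abs(rel[, 1] * u[2] - rel[, 2] * u[1])
  max(perp)
}

#' Endpoint accuracy errors across trials
#'
#' Per-trial absolute error is the Euclidean distance between the movement
#' endpoint and the target center. The condition-level absolute error is the
#' mean over trials; the variable error is the (n-1) standard deviation of the
#' per-trial absolute errors.
#'
#' @param endpoints numeric matrix (n_trials x 3) of movement endpoints, mm
#' @param target_point 3-D target center, mm
#' @return list with `absolute_error` (mean, mm), `variable_error` (SD, mm),
#'   `per_trial` (vector of per-trial absolute errors)
#' @export
accuracy_errors <- function(endpoints, target_point) {
  endpoints <- as.matrix(endpoints)
  if (nrow(endpoints) < 2L)
    stop("insufficient data: accuracy errors need at least 2 endpoints",
         call. = FALSE)
  err <- sqrt(colSums((t(endpoints) - target_point)^2))
  list(absolute_error = mean(err), variable_error = stats::sd(err),
       per_trial = err)
}

#' Time-normalize a per-sample series to 100 points of movement time
#'
#' Linearly interpolates a series (vector, or matrix with one column per
#' channel) onto 100 points: point k (k = 1..100) sits at fraction k/100 of
#' the movement time, measured from the movement start, so the 100th point
#' equals the end-of-movement sample and "1%" is the first normalized point.
#'
#' @param series numeric vector or matrix (rows = samples)
#' @param time sample times, s
#' @param bounds from [detect_bounds()]
#' @param n_points number of normalized points
#' @return numeric vector or matrix with `n_points` rows
#' @export
time_normalize <- function(series, time, bounds, n_points = 100L) {
  mat <- is.matrix(series)
  series <- as.matrix(series)
  if (nrow(series) != length(time))
    stop("series and time lengths differ", call. = FALSE)
  in_bounds <- bounds$end_index - bounds$start_index + 1L
  if (in_bounds < 2L)
    stop("insufficient data: fewer than 2 in-bounds samples", call. = FALSE)
  t0 <- time[bounds$start_index]
  mt <- time[bounds$end_index] - t0
  t_out <- t0 + (seq_len(n_points) / n_points) * mt
  out <- apply(series, 2L, function(col)
    stats::approx(time, col, xout = t_out, rule = 1)$y)
  out <- matrix(out, nrow = n_points, dimnames = list(NULL, colnames(series)))
  if (mat) out else drop(out)
}

#' Per-trial endpoint kinematic summary
#'
#' Runs the full endpoint battery on one trial: bounds detection, peak
#' velocity, acceleration/deceleration times, horizontal and vertical
#' curvature, and endpoint error.
#'
#' @inheritParams detect_bounds
#' @return one-row data.frame: `movement_time`, `peak_velocity_mm_s`,
#'   `acceleration_time`, `deceleration_time`, `horizontal_curvature_mm`,
#'   `vertical_curvature_mm`, `endpoint_error_mm`, plus `start_index`,
#'   `end_index`
#' @export
kinematic_summary <- function(traj, start_point, target_point,
                              speed_threshold = 25, radius = 10) {
  v <- tangential_velocity(traj)
  b <- detect_bounds(traj, v, start_point, target_point,
                     speed_threshold = speed_threshold, radius = radius)
  ph <- phase_times(traj, v, b)
  endpoint <- traj$position[b$end_index, ]
  data.frame(
    movement_time = b$movement_time,
    peak_velocity_mm_s = ph$peak_velocity,
    acceleration_time = ph$acceleration_time,
    deceleration_time = ph$deceleration_time,
    horizontal_curvature_mm = path_curvature(traj, b, start_point,
                                             target_point, "horizontal"),
    vertical_curvature_mm = path_curvature(traj, b, start_point,
                                           target_point, "vertical"),
    endpoint_error_mm = sqrt(sum((endpoint - target_point)^2)),
    start_index = b$start_index,
    end_index = b$end_index
  )
}
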