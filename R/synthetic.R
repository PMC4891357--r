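#' Default arm geometry used by the synthetic study design
#'
#' Upper arm 300 mm, forearm 250 mm, hand 80 mm, finger 70 mm: an approximate
#' adult right arm. Rod length is set per condition.
#'
#' @param rod_length rod length, mm
#' @return an [arm_geometry()] object
#' @export
default_geometry <- function(rod_length = 0) {
  arm_geometry(300, 250, 80, 70, rod_length = rod_length)
}

# Base start point in the shoulder frame (mm): on a table in front of and
# below the shoulder, reachable with the elbow flexed ~100 deg. The target
# sits 300 mm farther along +x in the same horizontal plane.
BASE_START <- c(250, 0, -250)
REACH_AMPLITUDE <- 300

#' Specification of one experimental condition
#'
#' One cell of the eight-condition design: four end-effector lengths (rod 0,
#' 100, 200, 300 mm) crossed with participant displacement. Start and target
#' points are expressed in the shoulder frame (+x toward the target). In
#' displaced conditions the participant's chair is moved away from the target
#' by exactly the rod length, so both points shift `rod_length` along +x in
#' the shoulder frame and the required tip amplitude stays 300 mm with the
#' same arm posture; in non-displaced conditions the points are fixed and
#' longer rods require smaller joint excursions.
#'
#' @param rod_length rod length, mm (0, 100, 200 or 300 in the study design;
#'   any non-negative value accepted)
#' @param displaced logical; was the participant displaced by the rod length?
#' @param n_trials trials per condition (study design: 25)
#' @param sample_rate sampling rate, Hz (study design: 100)
#' @param movement_time nominal reach duration, s
#' @param start_point,target_point optional 3-D points, mm; defaults follow
#'   the displacement rule above and are 300 mm apart
#' @return object of class `condition_spec`
#' @export
condition_spec <- function(rod_length, displaced, n_trials = 25L,
                           sample_rate = 100, movement_time = 0.6,
                           start_point = NULL, target_point = NULL) {
  shift <- if (displaced) rod_length else 0
  if (is.null(start_point)) start_point <- BASE_START + c(shift, 0, 0)
  if (is.null(target_point))
    target_point <- start_point + c(REACH_AMPLITUDE, 0, 0)
  stopifnot(rod_length >= 0, n_trials >= 1, sample_rate > 0,
            movement_time > 0)
  structure(list(
    rod_length = rod_length,
    displaced = isTRUE(displaced),
    n_trials = as.integer(n_trials),
    sample_rate = sample_rate,
    movement_time = movement_time,
    start_point = start_point,
    target_point = target_point,
    label = sprintf("rod%03d_%s", rod_length,
                    if (displaced) "displaced" else "fixed")
  ), class = "condition_spec")
}

#' The full eight-condition study design
#'
#' Four rod lengths (0, 100, 200, 300 mm) crossed with displaced / not
#' displaced seating, 25 trials each.
#'
#' @param ... passed to [condition_spec()] (e.g. `n_trials`, `movement_time`)
#' @return named list of 8 `condition_spec` objects
#' @export
study_design <- function(...) {
  conds <- list()
  for (displaced in c(FALSE, TRUE))
    for (rod in c(0, 100, 200, 300)) {
      cs <- condition_spec(rod, displaced, ...)
      conds[[cs$label]] <- cs
    }
  conds
}

#' Inter-trial joint variability model
#'
#' Zero-mean smooth joint-space deviations injected isotropically within the
#' Jacobian null space (per-dimension std `sigma_gev`, rad) and its orthogonal
#' complement (`sigma_ngev`, rad) at every instant of the reference
#' trajectory. With this construction the true goal-equivalent variance per
#' null-space dimension is `sigma_gev^2` and the true non-goal-equivalent
#' variance per orthogonal dimension is `sigma_ngev^2` at each injection
#' instant. Temporal smoothness is controlled by the standard deviation (s) of
#' a Gaussian smoothing kernel applied to the underlying white-noise process;
#' the smoothed process is rescaled to exactly unit instantaneous variance.
#'
#' Defaults: sigma_gev 2 degrees, sigma_ngev 0.5 degrees (a 4:1 ratio, giving
#' a true V_Ratio of 16), smoothness 0.4 s.
#'
#' @param sigma_gev null-space per-dimension deviation std, rad
#' @param sigma_ngev orthogonal-space per-dimension deviation std, rad
#' @param temporal_smoothness Gaussian kernel std, s
#' @param seed integer RNG seed
#' @return object of class `variability_model`
#' @export
variability_model <- function(sigma_gev = 2 * pi / 180,
                              sigma_ngev = 0.5 * pi / 180,
                              temporal_smoothness = 0.4,
                              seed = 1L) {
  stopifnot(sigma_gev >= 0, sigma_ngev >= 0, temporal_smoothness >= 0)
  structure(list(sigma_gev = sigma_gev, sigma_ngev = sigma_ngev,
                 temporal_smoothness = temporal_smoothness,
                 seed = as.integer(seed)),
            class = "variability_model")
}

#' Straight minimum-jerk reference trajectory
#'
#' A straight-line point-to-point path with the quintic minimum-jerk time
#' profile `10 tau^3 - 15 tau^4 + 6 tau^5`, preceded and followed by
#' stationary hold phases so that velocity-threshold bounds detection is
#' exercised. Peak speed is `1.875 * amplitude / movement_time`.
#'
#' @param start,target 3-D points, mm, distinct
#' @param movement_time reach duration, s
#' @param sample_rate sampling rate, Hz
#' @param hold_before,hold_after stationary hold durations, s
#' @return a [tip_trajectory()]; attributes `move_start_index` and
#'   `move_end_index` give the nominal first/last samples of the motion
#' @export
minimum_jerk_path <- function(start, target, movement_time, sample_rate = 100,
                              hold_before = 0.4, hold_after = 0.8) {
  start <- as.numeric(start); target <- as.numeric(target)
  if (length(start) != 3L || length(target) != 3L)
    stop("start and target must be 3-D points", call. = FALSE)
  if (sqrt(sum((target - start)^2)) < .Machine$double.eps)
    stop("start and target coincide", call. = FALSE)
  if (movement_time <= 0) stop("movement_time must be positive", call. = FALSE)
  dt <- 1 / sample_rate
  t_total <- hold_before + movement_time + hold_after
  time <- seq(0, t_total, by = dt)
  tau <- pmin(pmax((time - hold_before) / movement_time, 0), 1)
  s <- 10 * tau^3 - 15 * tau^4 + 6 * tau^5
  pos <- outer(s, target - start) + matrix(start, length(s), 3L, byrow = TRUE)
  traj <- tip_trajectory(time, pos)
  attr(traj, "move_start_index") <- which(tau > 0)[1L] - 1L
  attr(traj, "move_end_index") <- which(tau >= 1)[1L]
  traj
}

#' Damped least-squares inverse kinematics along a tip path
#'
#' Tracks a tip trajectory sample-to-sample from `initial_config`, solving
#' each sample with damped least-squares (Levenberg) iterations
#' `dq = J^T (J J^T + lambda^2 I)^{-1} r` until the tip residual is below
#' `tol` mm. Deterministic given its inputs.
#'
#' @param tip_path a [tip_trajectory()]
#' @param geometry an [arm_geometry()]
#' @param initial_config 9-vector seed posture, rad
#' @param lambda damping factor
#' @param max_iter iteration cap per sample
#' @param tol convergence residual, mm
#' @return matrix (n_samples x 9) of joint configurations, rad
#' @export
reference_joint_trajectory <- function(tip_path, geometry, initial_config,
                                       lambda = 0.01, max_iter = 200L,
                                       tol = 0.01) {
  stopifnot(inherits(tip_path, "tip_trajectory"))
  q <- as_joint_config(initial_config)
  targets <- tip_path$position
  reach <- total_reach(geometry)
  dist <- sqrt(rowSums(targets^2))
  bad <- which(dist >= reach)
  if (length(bad))
    stop("unreachable tip sample ", bad[1L], ": distance ",
         sprintf("%.1f", dist[bad[1L]]), " mm >= total chain length ",
         sprintf("%.1f", reach), " mm", call. = FALSE)
  out <- matrix(NA_real_, nrow(targets), 9L,
                dimnames = list(NULL, JOINT_NAMES))
  for (i in seq_len(nrow(targets))) {
    tgt <- targets[i, ]
    converged <- FALSE
    for (it in seq_len(max_iter)) {
      r <- tgt - forward_kinematics(q, geometry)
      if (sqrt(sum(r^2)) < tol) { converged <- TRUE; break }
      J <- compute_jacobian(q, geometry)
      dq <- crossprod(J, solve(tcrossprod(J) + lambda^2 * diag(3), r))
      q <- q + as.numeric(dq)
    }
    if (!converged) {
      r <- tgt - forward_kinematics(q, geometry)
      stop("inverse kinematics did not converge at sample ", i,
           " (residual ", sprintf("%.4g", sqrt(sum(r^2))), " mm)",
           call. = FALSE)
    }
    out[i, ] <- q
  }
  out
}

# Default seed posture: upper arm roughly alongside the body, elbow flexed
# ~100 deg, slight wrist/finger flexion. Inverse kinematics refines it onto
# the start point.
default_initial_config <- function() {
  c(0, 1.35, 0, 1.75, 0, 0, 0.25, 0, 0.25)
}

# T x T Gaussian smoothing matrix with rows rescaled to unit L2 norm, so that
# S %*% (unit white noise) has exactly unit variance at every sample,
# including the edges.
gaussian_smoother <- function(n, sd_samples) {
  if (sd_samples <= 0) return(diag(n))
  idx <- seq_len(n)
  S <- exp(-0.5 * outer(idx, idx, "-")^2 / sd_samples^2)
  S / sqrt(rowSums(S^2))
}

#' Nominal (noise-free) reference movement for a condition
#'
#' Builds the minimum-jerk tip path for the condition, solves the start
#' posture and then the whole path by damped least-squares inverse kinematics,
#' and packages everything the trial generator needs. Separated from
#' [generate_condition_dataset()] so replicate ensembles of the same condition
#' can reuse one reference.
#'
#' @param cond a [condition_spec()]
#' @param geometry an [arm_geometry()]; its `rod_length` must match the
#'   condition (use [default_geometry()] with `cond$rod_length`)
#' @param initial_config optional 9-vector seed posture
#' @return object of class `condition_reference`: list with `time`, `tip`
#'   (n x 3), `angles` (n x 9), `move_start_index`, `move_end_index`,
#'   `null_projectors` (per-sample 9x9 null-space projectors), `cond`,
#'   `geometry`
#' @export
condition_reference <- function(cond, geometry = NULL, initial_config = NULL) {
  stopifnot(inherits(cond, "condition_spec"))
  if (is.null(geometry)) geometry <- default_geometry(cond$rod_length)
  if (!isTRUE(all.equal(geometry$rod_length, cond$rod_length)))
    stop("geometry rod_length does not match the condition", call. = FALSE)
  if (is.null(initial_config)) initial_config <- default_initial_config()
  path <- minimum_jerk_path(cond$start_point, cond$target_point,
                            cond$movement_time, cond$sample_rate)
  # settle the seed posture onto the start point before tracking
  hold <- tip_trajectory(0:2 / cond$sample_rate,
                         matrix(cond$start_point, 3, 3, byrow = TRUE))
  q0 <- reference_joint_trajectory(hold, geometry, initial_config)[3L, ]
  angles <- reference_joint_trajectory(path, geometry, q0)
  n <- nrow(angles)
  p_null <- vector("list", n)
  for (i in seq_len(n)) {
    b <- subspace_bases(compute_jacobian(angles[i, ], geometry))
    p_null[[i]] <- tcrossprod(b$null_basis)
  }
  structure(list(
    time = path$time,
    tip = path$position,
    angles = angles,
    move_start_index = attr(path, "move_start_index"),
    move_end_index = attr(path, "move_end_index"),
    null_projectors = p_null,
    cond = cond,
    geometry = geometry
  ), class = "condition_reference")
}

#' Generate a synthetic trial ensemble for one condition
#'
#' Per trial, a smooth zero-mean joint-space deviation process is added to the
#' reference joint trajectory. At each sample the deviation is shaped so that
#' its component in the Jacobian null space (of the reference posture at that
#' sample) has per-dimension std `sigma_gev` and its component in the
#' orthogonal complement has per-dimension std `sigma_ngev`; tip trajectories
#' are recomputed from the perturbed angles by forward kinematics. Output is
#' reproducible given the model seed.
#'
#' @param cond a [condition_spec()]
#' @param geometry an [arm_geometry()] matching the condition's rod length
#' @param model a [variability_model()]
#' @param reference optional precomputed [condition_reference()]
#' @return object of class `trial_ensemble`: list with `time`, `angles`
#'   (array n_samples x 9 x n_trials, rad), `tips` (array n_samples x 3 x
#'   n_trials, mm), `reference`, `cond`, `geometry`, `model`
#' @export
generate_condition_dataset <- function(cond, geometry = NULL, model,
                                       reference = NULL) {
  stopifnot(inherits(cond, "condition_spec"),
            inherits(model, "variability_model"))
  if (is.null(reference)) reference <- condition_reference(cond, geometry)
  geometry <- reference$geometry
  n <- nrow(reference$angles)
  k <- cond$n_trials
  set.seed(model$seed)
  S <- gaussian_smoother(n, model$temporal_smoothness * cond$sample_rate)
  # white noise for all trials at once: n samples x (9 joints * k trials)
  W <- S %*% matrix(stats::rnorm(n * 9L * k), n, 9L * k)
  angles <- array(NA_real_, c(n, 9L, k),
                  dimnames = list(NULL, JOINT_NAMES, NULL))
  tips <- array(NA_real_, c(n, 3L, k), dimnames = list(NULL, c("x", "y", "z"), NULL))
  dg <- model$sigma_gev - model$sigma_ngev
  for (i in seq_len(n)) {
    # deviation-shaping matrix: sigma_ngev * I + (sigma_gev - sigma_ngev) * P_null
    M <- dg * reference$null_projectors[[i]]
    diag(M) <- diag(M) + model$sigma_ngev
    w_i <- matrix(W[i, ], 9L, k)         # 9 x trials
    angles[i, , ] <- reference$angles[i, ] + M %*% w_i
  }
  for (j in seq_len(k))
    tips[, , j] <- fk_trajectory(angles[, , j], geometry)
  structure(list(
    time = reference$time,
    angles = angles,
    tips = tips,
    reference = reference,
    cond = cond,
    geometry = geometry,
    model = model
  ), class = "trial_ensemble")
}

#' @export
print.trial_ensemble <- function(x, ...) {
  cat(sprintf(
    "Trial ensemble '%s': %d trials x %d samples at %g Hz (rod %g mm, %s)\n",
    x$cond$label, dim(x$angles)[3], dim(x$angles)[1], x$cond$sample_rate,
    x$cond$rod_length,
    if (x$cond$displaced) "displaced" else "not displaced"))
  invisible(x)
}

#' UCM decomposition of an ensemble at an injection instant
#'
#' Computes the UCM decomposition of inter-trial joint variability at a sample
#' of the ensemble's common time base -- by default the reference
#' end-of-movement sample, the instant at which the injected variance equals
#' the variability model exactly. The Jacobian is evaluated at the ensemble
#' mean configuration of that sample. This is the estimator used for
#' parameter-recovery checks; [analyze_ensemble()] provides the full
#' detection-based path used for measured data.
#'
#' @param ensemble a [generate_condition_dataset()] result
#' @param sample_index sample on the common time base; default the reference
#'   movement end
#' @return a `ucm_result` (see [ucm_decompose()])
#' @export
ensemble_ucm <- function(ensemble, sample_index = NULL) {
  stopifnot(inherits(ensemble, "trial_ensemble"))
  if (is.null(sample_index)) sample_index <- ensemble$reference$move_end_index
  configs <- t(ensemble$angles[sample_index, , ])   # trials x 9
  C <- joint_covariance(configs)
  bases <- subspace_bases(compute_jacobian(colMeans(configs),
                                           ensemble$geometry))
  ucm_decompose(C, bases)
}
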