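#' Joint-angle covariance across trials
#'
#' Unbiased (n-1 denominator) covariance of the nine joint angles across
#' trials at one movement instant.
#'
#' @param configs numeric matrix, one row per trial, 9 columns in
#'   [JOINT_NAMES] order (radians)
#' @return 9x9 symmetric covariance matrix, rad^2
#' @export
joint_covariance <- function(configs) {
  configs <- as.matrix(configs)
  if (ncol(configs) != 9L)
    stop("configs must have 9 columns (one per joint angle)", call. = FALSE)
  if (nrow(configs) < 2L)
    stop("insufficient data: joint covariance needs at least 2 trials",
         call. = FALSE)
  if (!all(is.finite(configs)))
    stop("configs contain non-finite angles", call. = FALSE)
  C <- stats::cov(configs)
  dimnames(C) <- list(JOINT_NAMES, JOINT_NAMES)
  C
}

# log that flags non-positive input as undefined (NA) instead of -Inf/NaN
safe_log <- function(x) {
  if (is.na(x) || x <= 0) NA_real_ else log(x)
}

new_ucm_result <- function(gev, ngev, n, d, singular) {
  # NGEV indistinguishable from zero at double precision (relative to the
  # total variance) leaves the ratio and the logs undefined, not infinite
  ngev_zero <- ngev <= 1e-12 * (gev + ngev)
  v_ratio <- if (!ngev_zero) gev / ngev else NA_real_
  structure(list(
    gev = gev,
    ngev = ngev,
    v_ratio = v_ratio,
    gev_log = safe_log(gev),
    ngev_log = if (ngev_zero) NA_real_ else safe_log(ngev),
    v_ratio_log = safe_log(v_ratio),
    n_joint_dims = n,
    n_task_dims = d,
    stabilized = gev > ngev,
    singularity_flag = singular
  ), class = "ucm_result")
}

#' @export
print.ucm_result <- function(x, ...) {
  cat(sprintf(
    "UCM decomposition (n = %d joint dims, d = %d task dims)%s\n",
    x$n_joint_dims, x$n_task_dims,
    if (x$singularity_flag) " [SINGULAR JACOBIAN]" else ""))
  cat(sprintf("  GEV  = %.6g rad^2/dim (log %.4g)\n", x$gev, x$gev_log))
  cat(sprintf("  NGEV = %.6g rad^2/dim (log %.4g)\n", x$ngev, x$ngev_log))
  cat(sprintf("  V_Ratio = %.6g (log %.4g)%s\n", x$v_ratio, x$v_ratio_log,
              if (isTRUE(x$stabilized)) "  -> tip position stabilized" else ""))
  invisible(x)
}

#' UCM decomposition of joint covariance into GEV and NGEV
#'
#' Projects a joint-angle covariance matrix onto the null space of the tip
#' Jacobian and its orthogonal complement, normalizing each part by its
#' subspace dimension:
#' \deqn{NGEV = trace(E_\perp^T C E_\perp) / d, \quad
#'       GEV  = trace(E_0^T C E_0) / (n - d), \quad
#'       V_{Ratio} = GEV / NGEV}
#' with \eqn{E_0} the null-space basis, \eqn{E_\perp} the orthogonal-space
#' basis, n = 9 joint dimensions and d = 3 task dimensions at a generic
#' posture. GEV is the goal-equivalent variability (joint variance that leaves
#' the tip position unchanged); NGEV the non-goal-equivalent variability
#' (variance that moves the tip). Natural-log values are attached for
#' distributional correction; V_Ratio > 1 (log > 0) indicates that the tip
#' position is stabilized by joint covariation.
#'
#' The bases must come from the Jacobian at the mean configuration of the same
#' ensemble that produced `C`. If NGEV is zero, `v_ratio` and the logs of
#' `ngev`/`v_ratio` are returned as `NA` (flagged undefined) rather than
#' infinite. Values inside `-1e-12` of zero are clipped to 0 with a warning.
#'
#' @param C 9x9 joint covariance matrix (see [joint_covariance()])
#' @param bases a [subspace_bases()] object from the Jacobian at the ensemble
#'   mean configuration
#' @return An object of class `ucm_result` with fields `gev`, `ngev`,
#'   `v_ratio`, `gev_log`, `ngev_log`, `v_ratio_log`, `n_joint_dims`,
#'   `n_task_dims`, `stabilized`, `singularity_flag`.
#' @export
ucm_decompose <- function(C, bases) {
  C <- as.matrix(C)
  if (!inherits(bases, "subspace_bases"))
    stop("bases must be a subspace_bases object", call. = FALSE)
  n <- nrow(C)
  if (n != ncol(C) || n != nrow(bases$null_basis))
    stop("dimension mismatch between covariance matrix and bases",
         call. = FALSE)
  if (max(abs(C - t(C))) > 1e-8 * max(1, max(abs(C))))
    stop("covariance matrix is not symmetric", call. = FALSE)
  d <- ncol(bases$orth_basis)
  ngev <- sum(diag(t(bases$orth_basis) %*% C %*% bases$orth_basis)) / d
  gev <- sum(diag(t(bases$null_basis) %*% C %*% bases$null_basis)) / (n - d)
  gev <- clip_negative(gev, "GEV")
  ngev <- clip_negative(ngev, "NGEV")
  new_ucm_result(gev, ngev, n = n, d = d, singular = bases$singular)
}

clip_negative <- function(x, label, tol = 1e-12) {
  if (x < 0) {
    if (x < -tol)
      stop(label, " is negative beyond tolerance: ", x, call. = FALSE)
    warning(label, " within -1e-12 of zero; clipped to 0", call. = FALSE)
    x <- 0
  }
  x
}

#' Brute-force UCM decomposition by explicit per-trial projection
#'
#' Independent verification path for [ucm_decompose()]: projects each trial's
#' deviation from the ensemble mean explicitly onto each basis, averages the
#' squared projection norms over trials (n-1 denominator, matching the
#' unbiased covariance), and divides by the subspace dimension. Must agree
#' with `ucm_decompose(joint_covariance(configs), bases)` to numerical
#' precision.
#'
#' @inheritParams joint_covariance
#' @inheritParams ucm_decompose
#' @return An object of class `ucm_result`.
#' @export
ucm_decompose_oracle <- function(configs, bases) {
  configs <- as.matrix(configs)
  if (nrow(configs) < 2L)
    stop("insufficient data: need at least 2 trials", call. = FALSE)
  if (!inherits(bases, "subspace_bases"))
    stop("bases must be a subspace_bases object", call. = FALSE)
  dev <- sweep(configs, 2L, colMeans(configs))
  m <- nrow(configs) - 1L
  d <- ncol(bases$orth_basis)
  n <- ncol(configs)
  ss_null <- sum((dev %*% bases$null_basis)^2) / m
  ss_orth <- sum((dev %*% bases$orth_basis)^2) / m
  new_ucm_result(gev = ss_null / (n - d), ngev = ss_orth / d,
                 n = n, d = d, singular = bases$singular)
}

#' Natural-log correction for UCM variables
#'
#' UCM variance measures are non-normally distributed across participants and
#' conditions; they are log-transformed before any statistical aggregation.
#' Non-positive input yields `NA` (an undefined-value flag) rather than an
#' error or `-Inf`, so aggregation never silently propagates non-finite
#' values.
#'
#' @param value positive scalar (or vector) to transform
#' @return natural logarithm; `NA` where `value <= 0`
#' @examples
#' log_transform(1)        # 0
#' log_transform(exp(1))   # 1
#' @export
log_transform <- function(value) {
  out <- suppressWarnings(log(value))
  out[!is.na(value) & value <= 0] <- NA_real_
  out
}

#' @export
as.data.frame.ucm_result <- function(x, ...) {
  data.frame(gev = x$gev, ngev = x$ngev, v_ratio = x$v_ratio,
             gev_log = x$gev_log, ngev_log = x$ngev_log,
             v_ratio_log = x$v_ratio_log,
             stabilized = x$stabilized,
             singularity_flag = x$singularity_flag)
}
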