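#' Canonical joint order of the nine-degree-of-freedom chain
#'
#' The package represents an arm-plus-rod configuration as a numeric vector of
#' nine angles (radians) in this fixed order. It is the joint-space axis order
#' used by every function in the package.
#'
#' @format Character vector of length 9.
#' @export
JOINT_NAMES <- c(
  "shoulder_plane_of_elevation",
  "shoulder_elevation",
  "shoulder_rotation",
  "elbow_flexion",
  "forearm_pronation",
  "wrist_abduction",
  "wrist_flexion",
  "finger_abduction",
  "finger_flexion"
)

#' Arm-plus-rod segment geometry
#'
#' Segment lengths of the upper-arm / forearm / hand / finger chain plus an
#' optional rigid rod attached collinearly to the distal finger segment
#' (`rod_length = 0` for bare index-finger conditions).
#'
#' @param upper_arm_length shoulder to elbow, mm
#' @param forearm_length elbow to wrist, mm
#' @param hand_length wrist to finger MCP joint, mm
#' @param finger_length MCP to fingertip, mm
#' @param rod_length rod beyond the fingertip, mm (0 when no rod is attached)
#' @return An object of class `arm_geometry` (a named list of the five
#'   lengths).
#' @examples
#' geom <- arm_geometry(300, 250, 80, 70, rod_length = 100)
#' total_reach(geom)  # 800
#' @export
arm_geometry <- function(upper_arm_length, forearm_length, hand_length,
                         finger_length, rod_length = 0) {
  g <- list(
    upper_arm_length = upper_arm_length,
    forearm_length = forearm_length,
    hand_length = hand_length,
    finger_length = finger_length,
    rod_length = rod_length
  )
  for (nm in names(g)) {
    v <- g[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v < 0)
      stop("arm_geometry: '", nm, "' must be a single finite non-negative number",
           call. = FALSE)
  }
  structure(g, class = "arm_geometry")
}

#' @rdname arm_geometry
#' @param geometry an `arm_geometry` object
#' @export
total_reach <- function(geometry) {
  stopifnot(inherits(geometry, "arm_geometry"))
  with(geometry, upper_arm_length + forearm_length + hand_length +
         finger_length + rod_length)
}

#' @export
print.arm_geometry <- function(x, ...) {
  cat("Arm-plus-rod geometry (mm):\n")
  for (nm in names(x)) cat(sprintf("  %-18s %g\n", nm, x[[nm]]))
  cat(sprintf("  %-18s %g\n", "total reach", total_reach(x)))
  invisible(x)
}

# Validate and strip a joint configuration to a bare numeric 9-vector.
as_joint_config <- function(config) {
  q <- as.numeric(config)
  if (length(q) != 9L)
    stop("joint configuration must have exactly 9 angles, got ", length(q),
         call. = FALSE)
  if (!all(is.finite(q)))
    stop("joint configuration contains non-finite angles", call. = FALSE)
  q
}

rot_x <- function(a) {
  c_ <- cos(a); s <- sin(a)
  matrix(c(1, 0, 0, 0, c_, s, 0, -s, c_), 3, 3)
}
rot_y <- function(a) {
  c_ <- cos(a); s <- sin(a)
  matrix(c(c_, 0, -s, 0, 1, 0, s, 0, c_), 3, 3)
}
rot_z <- function(a) {
  c_ <- cos(a); s <- sin(a)
  matrix(c(c_, s, 0, -s, c_, 0, 0, 0, 1), 3, 3)
}

#' Forward kinematics of the nine-degree-of-freedom arm-plus-rod chain
#'
#' Computes the Cartesian position (mm) of the end-effector tip -- the
#' fingertip, or the rod tip when `rod_length > 0` -- in the lab frame: origin
#' at the shoulder center, +x horizontal toward the target, +y to the
#' participant's left, +z vertical up.
#'
#' Joint convention (the package's own; zero posture = arm straightened along
#' +x with the rod collinear): the shoulder is an intrinsic
#' Rz(plane-of-elevation) Ry(elevation) Rx(axial-rotation) stack with positive
#' elevation lowering the arm from horizontal; elbow flexion and the wrist and
#' finger flexions rotate about the local -y axis so that positive flexion
#' bends the distal segment upward/forward from the hanging start posture;
#' forearm pronation rotates about the segment axis; wrist and finger
#' abductions rotate about the local +z axis. Each segment extends along its
#' local +x axis; the rod is a rigid collinear extension of the distal finger
#' segment.
#'
#' @param config numeric vector of 9 joint angles, radians, in [JOINT_NAMES]
#'   order
#' @param geometry an [arm_geometry()] object
#' @return numeric length-3 tip position, mm
#' @examples
#' geom <- arm_geometry(300, 250, 80, 70)
#' forward_kinematics(rep(0, 9), geom)  # c(700, 0, 0)
#' @export
forward_kinematics <- function(config, geometry) {
  q <- as_joint_config(config)
  stopifnot(inherits(geometry, "arm_geometry"))
  R <- rot_z(q[1]) %*% rot_y(q[2]) %*% rot_x(q[3])
  p <- R %*% c(geometry$upper_arm_length, 0, 0)
  R <- R %*% rot_y(-q[4]) %*% rot_x(q[5])
  p <- p + R %*% c(geometry$forearm_length, 0, 0)
  R <- R %*% rot_z(q[6]) %*% rot_y(-q[7])
  p <- p + R %*% c(geometry$hand_length, 0, 0)
  R <- R %*% rot_z(q[8]) %*% rot_y(-q[9])
  p <- p + R %*% c(geometry$finger_length + geometry$rod_length, 0, 0)
  as.numeric(p)
}

#' Forward kinematics along a joint trajectory
#'
#' @param angles numeric matrix, one row per time sample, 9 columns in
#'   [JOINT_NAMES] order
#' @inheritParams forward_kinematics
#' @return numeric matrix with the same number of rows and columns x, y, z
#'   (mm)
#' @export
fk_trajectory <- function(angles, geometry) {
  angles <- as.matrix(angles)
  if (ncol(angles) != 9L)
    stop("angle trajectory must have 9 columns", call. = FALSE)
  out <- matrix(NA_real_, nrow(angles), 3L,
                dimnames = list(NULL, c("x", "y", "z")))
  for (i in seq_len(nrow(angles)))
    out[i, ] <- forward_kinematics(angles[i, ], geometry)
  out
}

#' Jacobian of tip position with respect to the joint angles
#'
#' The 3x9 matrix of partial derivatives of the tip position (mm) with respect
#' to each joint angle (rad), evaluated at `config` by central finite
#' differences on [forward_kinematics()].
#'
#' @inheritParams forward_kinematics
#' @param h finite-difference step, radians
#' @return 3x9 numeric matrix; rows are x, y, z, columns follow [JOINT_NAMES]
#' @export
compute_jacobian <- function(config, geometry, h = 1e-6) {
  q <- as_joint_config(config)
  stopifnot(inherits(geometry, "arm_geometry"))
  J <- matrix(NA_real_, 3L, 9L, dimnames = list(c("x", "y", "z"), JOINT_NAMES))
  for (j in 1:9) {
    qp <- q; qp[j] <- qp[j] + h
    qm <- q; qm[j] <- qm[j] - h
    J[, j] <- (forward_kinematics(qp, geometry) -
                 forward_kinematics(qm, geometry)) / (2 * h)
  }
  J
}

#' Null-space and orthogonal-space bases of a tip Jacobian
#'
#' Splits the 9-D joint space into the null space of `J` (joint changes that
#' leave the tip fixed to first order -- the uncontrolled manifold's tangent
#' space) and its orthogonal complement, the row space of `J` (joint changes
#' that move the tip). Bases are orthonormal columns obtained from the
#' singular-value decomposition of `J`; singular values below
#' `tol * max(singular value)` are treated as zero. At a generic posture the
#' Jacobian has rank 3, giving a 9x6 null basis and a 9x3 orthogonal basis.
#'
#' A rank-deficient Jacobian (e.g. a fully stretched singular posture) is not
#' an error: the bases are returned with their actual dimensions and
#' `singular` is set to `TRUE` so the caller can decide how to proceed.
#'
#' @param J a 3x9 Jacobian matrix, finite entries
#' @param tol relative singular-value cutoff
#' @return An object of class `subspace_bases`: list with `null_basis`
#'   (9 x (9-rank)), `orth_basis` (9 x rank), `rank`, and `singular` flag.
#' @export
subspace_bases <- function(J, tol = 1e-10) {
  J <- as.matrix(J)
  if (nrow(J) != 3L || ncol(J) != 9L)
    stop("J must be a 3x9 matrix", call. = FALSE)
  if (!all(is.finite(J)))
    stop("J contains non-finite entries", call. = FALSE)
  sv <- svd(J, nu = 0, nv = 9)
  rank <- sum(sv$d > tol * max(sv$d, 0))
  structure(list(
    null_basis = sv$v[, setdiff(seq_len(9L), seq_len(rank)), drop = FALSE],
    orth_basis = sv$v[, seq_len(rank), drop = FALSE],
    rank = rank,
    singular = rank < 3L
  ), class = "subspace_bases")
}

#' @export
print.subspace_bases <- function(x, ...) {
  cat(sprintf("Jacobian subspace bases: rank %d, null dim %d%s\n", x$rank,
              ncol(x$null_basis), if (x$singular) " [SINGULAR]" else ""))
  invisible(x)
}
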