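#' Rigid 6D pose (camera-from-model)
#'
#' A pose maps model coordinates into camera coordinates:
#' `p_cam = R %*% p_model + t`. This convention matches PnP solvers and the
#' ADD metric's use of `R, t` on model points, and is used everywhere in the
#' package.
#'
#' @param rotation A 3x3 orthonormal rotation matrix, or a length-3
#'   axis-angle vector (axis * angle in radians).
#' @param translation Length-3 translation in model units.
#' @return An object of class `pose6d` with elements `R` (3x3) and `t`.
#' @examples
#' p <- pose6d(rotation = c(0, 0, pi / 2), translation = c(0, 0, 4))
#' p$R
#' @export
pose6d <- function(rotation = diag(3), translation = c(0, 0, 0)) {
  R <- if (is.matrix(rotation)) rotation else rotmat_from_axis_angle(rotation)
  stopifnot(is.matrix(R), all(dim(R) == c(3, 3)), length(translation) == 3)
  err <- max(abs(crossprod(R) - diag(3)))
  if (err > 1e-9) stop("rotation is not orthonormal (max |R'R - I| = ", err, ")")
  if (abs(det(R) - 1) > 1e-9) stop("rotation must have det +1")
  structure(list(R = R, t = as.numeric(translation)), class = "pose6d")
}

#' @export
print.pose6d <- function(x, ...) {
  aa <- axis_angle_from_rotmat(x$R)
  cat(sprintf("pose6d: angle %.3f deg, t = (%.4g, %.4g, %.4g)\n",
              sqrt(sum(aa^2)) * 180 / pi, x$t[1], x$t[2], x$t[3]))
  invisible(x)
}

#' Apply a pose to 3D points
#'
#' @param pose A `pose6d`.
#' @param points N x 3 matrix of model coordinates.
#' @return N x 3 matrix of camera coordinates.
#' @export
pose_apply <- function(pose, points) {
  points <- as_points3(points)
  sweep(points %*% t(pose$R), 2, pose$t, "+")
}

#' Compose and invert poses
#'
#' `pose_compose(a, b)` returns the pose applying `b` first, then `a`;
#' `pose_inverse(p)` maps camera coordinates back to model coordinates.
#'
#' @param a,b,p `pose6d` objects.
#' @return A `pose6d`.
#' @export
pose_compose <- function(a, b) {
  pose6d(a$R %*% b$R, as.numeric(a$R %*% b$t) + a$t)
}

#' @rdname pose_compose
#' @export
pose_inverse <- function(p) {
  pose6d(t(p$R), as.numeric(-t(p$R) %*% p$t))
}

# --- rotation parameterizations -------------------------------------------

#' Rotation conversions
#'
#' Conversions between 3x3 rotation matrices, axis-angle vectors
#' (Rodrigues: axis * angle, radians) and unit quaternions (w, x, y, z).
#' Round trips are accurate to < 1e-9.
#'
#' @param aa Length-3 axis-angle vector.
#' @return `rotmat_from_axis_angle`: a 3x3 rotation matrix.
#' @export
rotmat_from_axis_angle <- function(aa) {
  aa <- as.numeric(aa)
  th <- sqrt(sum(aa^2))
  Kx <- skew3(aa)
  if (th < 1e-8) {
    # second-order Taylor: exact to ~1e-16 at this angle
    diag(3) + Kx + 0.5 * Kx %*% Kx
  } else {
    diag(3) + sin(th) / th * Kx + (1 - cos(th)) / th^2 * Kx %*% Kx
  }
}

#' @rdname rotmat_from_axis_angle
#' @param R A 3x3 rotation matrix.
#' @return `axis_angle_from_rotmat`: a length-3 axis-angle vector with angle
#'   in `[0, pi]`.
#' @export
axis_angle_from_rotmat <- function(R) {
  q <- quat_from_rotmat(R)
  if (q[1] < 0) q <- -q
  sin_half <- sqrt(sum(q[2:4]^2))
  if (sin_half < 1e-12) return(c(0, 0, 0))
  th <- 2 * atan2(sin_half, q[1])
  q[2:4] / sin_half * th
}

#' @rdname rotmat_from_axis_angle
#' @return `quat_from_rotmat`: a unit quaternion `(w, x, y, z)`.
#' @export
quat_from_rotmat <- function(R) {
  tr <- R[1, 1] + R[2, 2] + R[3, 3]
  if (tr > 0) {
    s <- sqrt(tr + 1) * 2
    q <- c(0.25 * s, (R[3, 2] - R[2, 3]) / s, (R[1, 3] - R[3, 1]) / s,
           (R[2, 1] - R[1, 2]) / s)
  } else if (R[1, 1] >= R[2, 2] && R[1, 1] >= R[3, 3]) {
    s <- sqrt(1 + R[1, 1] - R[2, 2] - R[3, 3]) * 2
    q <- c((R[3, 2] - R[2, 3]) / s, 0.25 * s, (R[1, 2] + R[2, 1]) / s,
           (R[1, 3] + R[3, 1]) / s)
  } else if (R[2, 2] >= R[3, 3]) {
    s <- sqrt(1 + R[2, 2] - R[1, 1] - R[3, 3]) * 2
    q <- c((R[1, 3] - R[3, 1]) / s, (R[1, 2] + R[2, 1]) / s, 0.25 * s,
           (R[2, 3] + R[3, 2]) / s)
  } else {
    s <- sqrt(1 + R[3, 3] - R[1, 1] - R[2, 2]) * 2
    q <- c((R[2, 1] - R[1, 2]) / s, (R[1, 3] + R[3, 1]) / s,
           (R[2, 3] + R[3, 2]) / s, 0.25 * s)
  }
  q / sqrt(sum(q^2))
}

#' @rdname rotmat_from_axis_angle
#' @param q Unit quaternion `(w, x, y, z)`.
#' @return `rotmat_from_quat`: a 3x3 rotation matrix.
#' @export
rotmat_from_quat <- function(q) {
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y + w * z),     2 * (x * z - w * y),
    2 * (x * y - w * z), 1 - 2 * (x^2 + z^2),     2 * (y * z + w * x),
    2 * (x * z + w * y), 2 * (y * z - w * x),     1 - 2 * (x^2 + y^2)
  ), 3, 3)
}

#' Geodesic angle between two rotations, in degrees
#'
#' `acos((trace(Ra' Rb) - 1) / 2)` clamped to `[0, 180]`; a standard
#' diagnostic for rotation recovery error.
#'
#' @param a,b `pose6d` objects (only their rotations are used).
#' @return Angle in degrees.
#' @export
rotation_geodesic_deg <- function(a, b) {
  cth <- (sum(diag(crossprod(a$R, b$R))) - 1) / 2
  acos(min(1, max(-1, cth))) * 180 / pi
}

# pose <-> flat 6-vector (axis-angle, translation), the solver/optimizer
# parameterization used by PnP and pose refinement. pose_from_vec6 skips the
# orthonormality validation (Rodrigues output is orthonormal by construction)
# since it sits on the solver hot path.
pose_to_vec6 <- function(pose) c(axis_angle_from_rotmat(pose$R), pose$t)
pose_from_vec6 <- function(v) {
  structure(list(R = rotmat_from_axis_angle(v[1:3]), t = as.numeric(v[4:6])),
            class = "pose6d")
}

#' Pose interchange records
#'
#' Poses are serialized as `{quaternion wxyz, translation xyz,
#' convention: "camera_from_model"}` in all manifests and reports.
#'
#' @param pose A `pose6d`.
#' @return `pose_to_record`: a named list; `pose_from_record`: a `pose6d`.
#' @export
pose_to_record <- function(pose) {
  list(quaternion_wxyz = as.numeric(quat_from_rotmat(pose$R)),
       translation_xyz = as.numeric(pose$t),
       convention = "camera_from_model")
}

#' @rdname pose_to_record
#' @param rec A record produced by `pose_to_record` (possibly via JSON).
#' @export
pose_from_record <- function(rec) {
  stopifnot(identical(rec$convention, "camera_from_model"))
  pose6d(rotmat_from_quat(as.numeric(rec$quaternion_wxyz)),
         as.numeric(rec$translation_xyz))
}

# --- internal helpers ------------------------------------------------------

skew3 <- function(v) {
  matrix(c(0, v[3], -v[2],
           -v[3], 0, v[1],
           v[2], -v[1], 0), 3, 3)
}

as_points3 <- function(points) {
  if (is.null(dim(points))) points <- matrix(points, ncol = 3, byrow = TRUE)
  storage.mode(points) <- "double"
  stopifnot(ncol(points) == 3)
  points
}

crossv <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}
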