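#' Pinhole projection of 3D points
#'
#' Projects model-space points into pixel coordinates under a pose:
#' `u = fx * Xc / Zc + cx`, `v = fy * Yc / Zc + cy` with
#' `(Xc, Yc, Zc) = R p + t`. Points at or behind the camera plane
#' (`Zc <= depth_eps`) are flagged invisible, never silently projected, as
#' are points projecting outside the image bounds.
#'
#' @param points N x 3 matrix of model coordinates, or a `feature_points3d`.
#' @param pose A `pose6d` (camera-from-model).
#' @param K A `camera_intrinsics`.
#' @param depth_eps Minimum camera-frame depth (model units).
#' @return A `projections2d` object: list with `uv` (N x 2, continuous
#'   pixels; `NA` where depth-invalid), `visible` (logical) and `depth`.
#' @examples
#' K <- camera_intrinsics(100, 100, 320, 240, 640, 480)
#' project_points(c(0, 0, 2), pose6d(), K)$uv   # principal point
#' @export
project_points <- function(points, pose, K, depth_eps = 1e-6) {
  if (inherits(points, "feature_points3d")) points <- points$points
  points <- as_points3(points)
  pc <- pose_apply(pose, points)
  z <- pc[, 3]
  ok <- z > depth_eps
  uv <- matrix(NA_real_, nrow(points), 2)
  uv[ok, 1] <- K$fx * pc[ok, 1] / z[ok] + K$cx
  uv[ok, 2] <- K$fy * pc[ok, 2] / z[ok] + K$cy
  visible <- ok & !is.na(uv[, 1]) &
    uv[, 1] >= 0 & uv[, 1] < K$width & uv[, 2] >= 0 & uv[, 2] < K$height
  structure(list(uv = uv, visible = visible, depth = z),
            class = "projections2d")
}

#' @export
print.projections2d <- function(x, ...) {
  cat(sprintf("projections2d: %d points, %d visible\n",
              nrow(x$uv), sum(x$visible)))
  invisible(x)
}

#' Back-project a pixel at known depth
#'
#' Inverse of [project_points()] given the camera-frame depth; returns the
#' model-space point.
#'
#' @param uv Length-2 pixel coordinates.
#' @param depth Camera-frame depth `Zc`.
#' @inheritParams project_points
#' @return Length-3 model-space point.
#' @export
unproject_pixel <- function(uv, depth, pose, K) {
  pc <- c((uv[1] - K$cx) / K$fx * depth, (uv[2] - K$cy) / K$fy * depth, depth)
  as.numeric(t(pose$R) %*% (pc - pose$t))
}

# Jacobian of the projection of each point w.r.t. the 6-vector pose
# parameterization (axis-angle, translation). Returns list(uv, depth, J)
# where J is N x 2 x 6. Core of the PnP solver and of all pose gradients;
# fully vectorized over points (hot path of the LM iterations).
projection_jacobian <- function(points, pose, K, depth_eps = 1e-6) {
  points <- as_points3(points)
  n <- nrow(points)
  aa <- axis_angle_from_rotmat(pose$R)
  pc <- pose_apply(pose, points)
  z <- pc[, 3]
  ok <- z > depth_eps
  X <- pc[, 1]; Y <- pc[, 2]; Z <- z
  uv <- matrix(NA_real_, n, 2)
  uv[ok, 1] <- K$fx * X[ok] / Z[ok] + K$cx
  uv[ok, 2] <- K$fy * Y[ok] / Z[ok] + K$cy

  # d(pc)/d(aa_i) for all points at once: D_i = dR/d(aa_i), rows A_i = D_i p
  th2 <- sum(aa^2)
  Dlist <- vector("list", 3)
  if (th2 < 1e-16) {
    for (i in 1:3) {
      ei <- c(0, 0, 0); ei[i] <- 1
      Dlist[[i]] <- skew3(ei)  # d(Rp)/d(aa_i) = e_i x p = skew(e_i) p
    }
  } else {
    R <- pose$R
    ImR <- diag(3) - R
    for (i in 1:3) {
      ei <- c(0, 0, 0); ei[i] <- 1
      wi <- aa[i] * aa + crossv(aa, as.numeric(ImR %*% ei))
      Dlist[[i]] <- skew3(wi / th2) %*% R
    }
  }
  J <- array(0, c(n, 2, 6))
  Z2 <- Z^2
  fu <- K$fx / Z; fv <- K$fy / Z
  gu <- -K$fx * X / Z2; gv <- -K$fy * Y / Z2
  for (i in 1:3) {
    A <- points %*% t(Dlist[[i]])   # n x 3
    J[, 1, i] <- fu * A[, 1] + gu * A[, 3]
    J[, 2, i] <- fv * A[, 2] + gv * A[, 3]
  }
  J[, 1, 4] <- fu; J[, 1, 6] <- gu
  J[, 2, 5] <- fv; J[, 2, 6] <- gv
  J[!ok, , ] <- 0
  list(uv = uv, depth = z, J = J)
}
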