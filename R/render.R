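#' Hard silhouette rasterization
#'
#' Rasterizes the binary silhouette of a posed mesh under a pinhole camera:
#' a pixel is foreground iff its center lies inside the projection of any
#' front-of-camera face. Faces crossing the near plane (`Z = depth_eps`) are
#' clipped, not dropped, so silhouettes do not pop during pose optimization.
#'
#' @param mesh A `tri_mesh`.
#' @param pose A `pose6d`.
#' @param K A `camera_intrinsics` (sets the mask resolution).
#' @param depth_eps Near-plane depth in model units.
#' @return An integer `height x width` matrix of 0/1 values (class
#'   `mask_image`, binary mode). A warning is raised if the mask is empty
#'   (e.g. whole mesh behind the camera).
#' @export
rasterize_hard <- function(mesh, pose, K, depth_eps = 1e-6) {
  cp <- clip_and_project(mesh, pose, K, depth_eps)
  m <- if (nrow(cp$faces) == 0) {
    matrix(0L, K$height, K$width)
  } else {
    .cpp_raster_hard(cp$uv, cp$faces - 1L, K$width, K$height)
  }
  if (!any(m == 1L)) warning("rasterized mask is empty")
  mask_image(m, mode = "binary")
}

#' Soft (differentiable) silhouette rasterization
#'
#' Per-pixel occupancy `1 - prod_f (1 - sigmoid(sharpness * d_f))`, where
#' `d_f` is the signed 2D distance (px, positive inside) from the pixel
#' center to projected face `f`. Values lie in (0, 1), are differentiable
#' w.r.t. the pose, and approach the hard mask as `sharpness` grows. Faces
#' farther than `cutoff_px` from a pixel are skipped; the default
#' (`8 / sharpness`) keeps the truncation error below sigmoid(-8) ~ 3e-4
#' per face.
#'
#' @inheritParams rasterize_hard
#' @param sharpness Edge sharpness in 1/px (default 10).
#' @param cutoff_px Face influence radius in px.
#' @return A numeric `height x width` matrix in (0, 1) (class `mask_image`,
#'   soft mode).
#' @export
rasterize_soft <- function(mesh, pose, K, sharpness = 10,
                           cutoff_px = 8 / sharpness, depth_eps = 1e-6) {
  stopifnot(sharpness > 0)
  cp <- clip_and_project(mesh, pose, K, depth_eps)
  m <- if (nrow(cp$faces) == 0) {
    matrix(0, K$height, K$width)
  } else {
    .cpp_raster_soft(cp$uv, cp$faces - 1L, K$width, K$height,
                     sharpness, cutoff_px)
  }
  if (max(m) < 0.5) warning("soft mask has no interior pixels")
  mask_image(m, mode = "soft")
}

#' Silhouette rendering loss
#'
#' Mean squared error between a rendered (soft) foreground mask and an
#' observed (binary) segmentation mask — the global contour-consistency term
#' of the training objective and of silhouette-based pose refinement.
#'
#' @param mr Rendered mask (soft or binary).
#' @param ms Observed mask (binary), same shape.
#' @return Mean over all pixels of the squared difference.
#' @export
render_loss <- function(mr, ms) {
  if (!all(dim(mr) == dim(ms))) stop("mask shapes differ")
  mean((as.numeric(mr) - as.numeric(ms))^2)
}

#' Rendering loss and its pose gradient
#'
#' Evaluates `render_loss(rasterize_soft(mesh, pose, K), target)` together
#' with its analytic gradient w.r.t. the 6-vector pose parameterization
#' (axis-angle, translation). The gradient flows through the signed-distance
#' soft rasterizer to the projected vertices, then through the projection
#' Jacobian; vertices introduced by near-plane clipping are treated as fixed
#' model points (exact away from the near plane).
#'
#' @inheritParams rasterize_soft
#' @param target Binary target mask at the camera resolution.
#' @return List with `loss` (scalar), `grad` (length 6) and `mask`.
#' @export
render_loss_pose_grad <- function(mesh, pose, K, target, sharpness = 10,
                                  cutoff_px = 8 / sharpness,
                                  depth_eps = 1e-6) {
  if (!all(dim(target) == c(K$height, K$width))) stop("mask shapes differ")
  cp <- clip_and_project(mesh, pose, K, depth_eps)
  if (nrow(cp$faces) == 0) {
    return(list(loss = mean(as.numeric(target)^2), grad = rep(0, 6),
                mask = mask_image(matrix(0, K$height, K$width), "soft")))
  }
  m <- .cpp_raster_soft(cp$uv, cp$faces - 1L, K$width, K$height,
                        sharpness, cutoff_px)
  diffm <- m - as.numeric(target)
  loss <- mean(diffm^2)
  grad_mask <- matrix(2 * diffm / length(m), K$height, K$width)
  duv <- .cpp_raster_soft_vjp(cp$uv, cp$faces - 1L, K$width, K$height,
                              sharpness, cutoff_px, grad_mask)
  pj <- projection_jacobian(cp$model_points, pose, K, depth_eps)
  g <- rep(0, 6)
  for (k in seq_len(nrow(duv))) {
    if (is.na(pj$uv[k, 1])) next
    g <- g + as.numeric(duv[k, ] %*% pj$J[k, , ])
  }
  list(loss = loss, grad = g, mask = mask_image(m, "soft"))
}

# Transform mesh to camera frame, clip faces against the near plane
# Z = depth_eps (partially-behind faces are clipped into 1-2 sub-triangles),
# and project every needed vertex. Returns uv (n x 2), faces (1-based),
# and the model-space coordinates of all projected vertices (clip points are
# interpolated in model space).
clip_and_project <- function(mesh, pose, K, depth_eps = 1e-6) {
  v_model <- mesh$vertices
  pc <- pose_apply(pose, v_model)
  z <- pc[, 3]
  faces <- mesh$faces
  front <- matrix(z[faces] > depth_eps, ncol = 3)
  n_front <- rowSums(front)
  keep <- which(n_front == 3L)
  cross <- which(n_front > 0L & n_front < 3L)

  out_faces <- faces[keep, , drop = FALSE]
  extra_model <- NULL
  extra_faces <- NULL
  for (f in cross) {
    idx <- faces[f, ]
    poly_m <- list()  # model-space polygon after clipping
    for (e in 1:3) {
      i <- idx[e]; j <- idx[e %% 3 + 1]
      zi <- z[i]; zj <- z[j]
      if (zi > depth_eps) poly_m[[length(poly_m) + 1]] <- v_model[i, ]
      if ((zi > depth_eps) != (zj > depth_eps)) {
        s <- (depth_eps - zi) / (zj - zi)
        poly_m[[length(poly_m) + 1]] <-
          v_model[i, ] + s * (v_model[j, ] - v_model[i, ])
      }
    }
    if (length(poly_m) < 3) next
    base <- if (is.null(extra_model)) 0L else nrow(extra_model)
    extra_model <- rbind(extra_model, do.call(rbind, poly_m))
    for (k in seq_len(length(poly_m) - 2)) {
      extra_faces <- rbind(extra_faces, base + c(1L, k + 1L, k + 2L))
    }
  }

  used <- sort(unique(as.integer(out_faces)))
  remap <- integer(nrow(v_model))
  remap[used] <- seq_along(used)
  model_points <- v_model[used, , drop = FALSE]
  faces1 <- if (nrow(out_faces)) matrix(remap[out_faces], ncol = 3) else
    matrix(integer(0), 0, 3)
  if (!is.null(extra_model)) {
    extra_faces <- extra_faces + nrow(model_points)
    model_points <- rbind(model_points, extra_model)
    faces1 <- rbind(faces1, extra_faces)
  }
  if (nrow(faces1) == 0) {
    return(list(uv = matrix(0, 0, 2), faces = matrix(integer(0), 0, 3),
                model_points = matrix(0, 0, 3)))
  }
  pc2 <- pose_apply(pose, model_points)
  z2 <- pmax(pc2[, 3], depth_eps)
  uv <- cbind(K$fx * pc2[, 1] / z2 + K$cx, K$fy * pc2[, 2] / z2 + K$cy)
  list(uv = uv, faces = faces1, model_points = model_points)
}
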