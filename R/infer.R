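#' Pose inference from a silhouette mask
#'
#' The two-stage inference pipeline: the heatmap network predicts the image
#' projections of the implicit 3D keypoints (via soft-argmax), then the PnP
#' layer estimates the pose. Keypoints whose heatmap peak confidence falls
#' below `min_confidence` are dropped; with fewer than 4 confident keypoints
#' no PnP solve is possible and the result is flagged (use [refine_pose()]
#' from an external initialization in that case).
#'
#' @param mask A binary `mask_image` at the checkpoint's input resolution.
#' @param checkpoint A `maskpose_checkpoint` (or list with `params`,
#'   `config`, `keypoints3d`).
#' @param mesh The instrument `tri_mesh` (for the reprojected overlay).
#' @param K A `camera_intrinsics`.
#' @param min_confidence Minimum heatmap peak value for a keypoint to enter
#'   the solve.
#' @param overlay Also rasterize the estimated pose and report its IOU
#'   against the input mask?
#' @param refine Follow the PnP estimate with silhouette-consistency
#'   refinement ([refine_pose()]) - the full method including its
#'   differentiable-rendering pose estimation stage.
#' @param refine_iters Gradient steps per sharpness level when refining.
#' @return A `pose_estimate`: list with `pose` (or `NULL` on failure),
#'   `keypoints` (uv + confidence), `solution`, `ok`, and optionally
#'   `reprojected`/`iou`.
#' @export
infer_pose <- function(mask, checkpoint, mesh, K, min_confidence = 0.2,
                       overlay = TRUE, refine = FALSE, refine_iters = 40L) {
  config <- checkpoint$config
  z <- checkpoint$keypoints3d
  if (is.null(z)) stop("checkpoint carries no 3D keypoints")
  if (all(as.integer(mask) == 0L)) {
    return(structure(list(pose = NULL, keypoints = NULL, solution = NULL,
                          ok = FALSE, reason = "empty input mask"),
                     class = "pose_estimate"))
  }
  hm <- backbone_forward(mask, config, checkpoint$params)
  conf <- apply(hm, 3, max)
  proj <- regress_coordinates(hm, tau = config$tau, stride = config$stride)
  usable <- proj$visible & conf >= min_confidence
  if (sum(usable) < 4) {
    warning("fewer than 4 confident keypoints; falling back to ",
            "refinement-only pose search")
    fb <- refinement_only_pose(mask, mesh, K, refine_iters = refine_iters)
    if (is.null(fb)) {
      return(structure(list(pose = NULL,
                            keypoints = list(uv = proj$uv, confidence = conf),
                            solution = NULL, ok = FALSE,
                            reason = "too few confident keypoints"),
                       class = "pose_estimate"))
    }
    out <- list(pose = fb, keypoints = list(uv = proj$uv, confidence = conf),
                solution = NULL, ok = TRUE, fallback = "refinement_only")
    if (overlay) {
      out$reprojected <- suppressWarnings(rasterize_hard(mesh, fb, K))
      out$iou <- iou(out$reprojected, mask)
    }
    return(structure(out, class = "pose_estimate"))
  }
  # force the rotation restarts so the second sheet of a near-planar
  # configuration is found, then disambiguate candidates by contour
  # consistency (the rendering loss), as the global silhouette term does
  # during training
  layer <- bpnp_layer(proj$uv, z, K, visible = usable, restart_tol = 0)
  cands <- layer$solution$candidates
  # silhouette-aligned variants: keep each candidate rotation but re-fit the
  # translation from the observed mask (centroid ray for x, y; area ratio
  # for depth) - rescues solutions whose depth collapsed
  for (k in seq_along(cands)) {
    al <- align_translation_to_mask(mesh, cands[[k]]$pose, K, mask)
    if (!is.null(al)) {
      cands[[length(cands) + 1]] <- list(pose = al, converged = TRUE,
                                         residual = Inf)
    }
  }
  if (length(cands) > 1) {
    # score by mask overlap, not MSE: a grossly wrong pose renders a tiny or
    # empty silhouette whose MSE against the mask is deceptively small
    sc <- vapply(cands, function(s) {
      m <- tryCatch(suppressWarnings(rasterize_hard(mesh, s$pose, K)),
                    error = function(e) NULL)
      if (is.null(m)) -Inf else suppressWarnings(iou(m, mask))
    }, 0.0)
    pick <- cands[[which.max(sc)]]
    if (pick$converged && max(sc) > 0) {
      layer$pose <- pick$pose
      layer$solution$pose <- pick$pose
      layer$solution$residual <- pick$residual
    }
  }
  if (refine && !is.null(layer$pose)) {
    # anchor the silhouette refinement with the predicted keypoints at the
    # training-time reprojection weight
    ref <- tryCatch(refine_pose(mask, layer$pose, mesh, K,
                                iters = refine_iters,
                                keypoints = z[usable, , drop = FALSE],
                                target_uv = proj$uv[usable, , drop = FALSE],
                                alpha = 5e-5),
                    error = function(e) NULL)
    if (!is.null(ref)) layer$pose <- ref$pose
  }
  out <- list(pose = layer$pose,
              keypoints = list(uv = proj$uv, confidence = conf,
                               used = usable),
              solution = layer$solution, ok = layer$solution$converged)
  if (overlay && !is.null(out$pose)) {
    out$reprojected <- suppressWarnings(rasterize_hard(mesh, out$pose, K))
    out$iou <- iou(out$reprojected, mask)
  }
  structure(out, class = "pose_estimate")
}

#' @export
print.pose_estimate <- function(x, ...) {
  if (!x$ok) {
    cat("pose_estimate: FAILED (", x$reason %||% "solver not converged",
        ")\n", sep = "")
  } else {
    cat("pose_estimate:\n  ")
    print(x$pose)
    if (!is.null(x$iou)) cat(sprintf("  reprojection IOU: %.4f\n", x$iou))
  }
  invisible(x)
}

# Refinement-only coarse search: probe a fixed set of rotations with the
# translation aligned to the observed silhouette, keep the best-overlapping
# candidate and refine it against the contour.
refinement_only_pose <- function(mask, mesh, K, refine_iters = 40L) {
  if (!any(as.integer(mask) == 1L)) return(NULL)
  diam <- mesh_diameter(mesh)
  base <- pose6d(diag(3), c(0, 0, 5 * diam))
  best <- NULL; best_iou <- 0
  rots <- c(list(c(0, 0, 0)), restart_rotations(),
            list(c(pi / 2, pi / 2, 0), c(-pi / 2, 0, pi / 2)))
  for (aa in rots) {
    cand <- pose6d(rotmat_from_axis_angle(aa) %*% base$R, base$t)
    al <- align_translation_to_mask(mesh, cand, K, mask)
    if (is.null(al)) next
    al <- align_translation_to_mask(mesh, al, K, mask) %||% al
    m <- tryCatch(suppressWarnings(rasterize_hard(mesh, al, K)),
                  error = function(e) NULL)
    if (is.null(m)) next
    sc <- suppressWarnings(iou(m, mask))
    if (sc > best_iou) { best <- al; best_iou <- sc }
  }
  if (is.null(best)) return(NULL)
  ref <- tryCatch(refine_pose(mask, best, mesh, K, iters = refine_iters),
                  error = function(e) NULL)
  if (is.null(ref)) best else ref$pose
}

# Re-fit a pose's translation from the observed silhouette: scale depth by
# the square root of the rendered/observed area ratio, then move the object
# onto the centroid ray of the mask. Returns NULL if either mask is empty.
align_translation_to_mask <- function(mesh, pose, K, mask) {
  obs <- which(as.integer(mask) == 1L)
  if (length(obs) == 0) return(NULL)
  rend <- tryCatch(suppressWarnings(rasterize_hard(mesh, pose, K)),
                   error = function(e) NULL)
  if (is.null(rend)) return(NULL)
  a_r <- sum(rend)
  if (a_r < 3) return(NULL)
  dims <- dim(mask)
  idx <- arrayInd(obs, dims)
  u_obs <- mean(idx[, 2]) - 1  # 0-based pixel coords
  v_obs <- mean(idx[, 1]) - 1
  z_new <- pose$t[3] * sqrt(a_r / length(obs))
  t_new <- c((u_obs - K$cx) / K$fx * z_new,
             (v_obs - K$cy) / K$fy * z_new,
             z_new)
  if (t_new[3] <= 0) return(NULL)
  pose6d(pose$R, t_new)
}

#' Silhouette-based pose refinement
#'
#' Gradient-based minimization of the rendering loss
#' `beta * MSE(soft_render(pose), mask)` (optionally plus a keypoint
#' reprojection term) over the pose, starting from `init`. Uses a
#' coarse-to-fine sharpness sweep with backtracking line search, so the
#' reported loss trace (at the final sharpness) is non-increasing; if no
#' improvement is possible the initial pose is returned unchanged.
#'
#' @param mask Observed binary `mask_image`.
#' @param init Initial `pose6d` (must render a non-empty, overlapping
#'   silhouette).
#' @param mesh The instrument `tri_mesh`.
#' @param K A `camera_intrinsics`.
#' @param iters Quasi-Newton iteration cap per sharpness level.
#' @param sharpness_levels Coarse-to-fine soft-rasterizer sharpness sweep
#'   (1/px). Low sharpness widens the attraction basin; the top levels
#'   tighten the optimum onto the observed contour.
#' @param beta Weight of the rendering loss.
#' @param keypoints,target_uv Optional implicit keypoints and their target
#'   projections to add an `alpha`-weighted reprojection term.
#' @param alpha Weight of the optional keypoint term.
#' @param polish_steps Monotone line-searched gradient steps at the final
#'   sharpness (their accepted losses form the reported `trace`).
#' @return A `pose_refinement`: list with `pose`, `loss` (final rendering
#'   loss), `trace` (non-increasing accepted-step losses at the final
#'   sharpness), `converged`.
#' @export
refine_pose <- function(mask, init, mesh, K, iters = 80L,
                        sharpness_levels = c(1, 3, 10, 20, 40), beta = 1.2,
                        keypoints = NULL, target_uv = NULL, alpha = 0,
                        polish_steps = 15L) {
  final_sharp <- tail(sharpness_levels, 1)
  soft0 <- suppressWarnings(rasterize_soft(mesh, init, K, sharpness = final_sharp))
  if (max(soft0) < 0.5) {
    stop("initial pose renders no silhouette; a coarse search is needed first")
  }
  hard0 <- (matrix(as.numeric(soft0), nrow(soft0)) >= 0.5) + 0L
  if (sum(hard0 & (as.integer(mask) == 1L)) == 0) {
    stop("initial silhouette does not overlap the mask; refine needs a coarser search")
  }
  target <- matrix(as.numeric(mask), nrow(mask))
  obj <- function(v, sharp) {
    pose <- pose_from_vec6(v)
    rl <- render_loss_pose_grad(mesh, pose, K, target, sharpness = sharp)
    loss <- beta * rl$loss
    grad <- beta * rl$grad
    if (!is.null(keypoints) && alpha > 0) {
      pb <- pnp_problem(target_uv, keypoints, K)
      lg <- reprojection_loss_grads(pb, pose)
      loss <- loss + alpha * lg$loss
      grad <- grad + alpha * lg$dpose
    }
    list(loss = loss, grad = grad)
  }
  v <- pose_to_vec6(init)
  # coarse-to-fine quasi-Newton sweep
  for (sharp in sharpness_levels) {
    o <- tryCatch(
      stats::optim(v,
                   fn = function(vv) obj(vv, sharp)$loss,
                   gr = function(vv) obj(vv, sharp)$grad,
                   method = "BFGS",
                   control = list(maxit = iters, reltol = 1e-14)),
      error = function(e) NULL)
    if (!is.null(o)) v <- o$par
  }
  # monotone line-searched polish at the final sharpness: the trace of
  # accepted losses is non-increasing by construction
  cur <- obj(v, final_sharp)
  trace <- cur$loss
  step <- 1e-3
  for (it in seq_len(polish_steps)) {
    g <- cur$grad
    gn <- sqrt(sum(g^2))
    if (gn < 1e-14) break
    improved <- FALSE
    for (bt in 1:15) {
      v_try <- v - step * g / gn
      cand <- tryCatch(obj(v_try, final_sharp), error = function(e) NULL)
      if (!is.null(cand) && cand$loss < cur$loss) {
        v <- v_try; cur <- cand
        step <- step * 1.8
        improved <- TRUE
        break
      }
      step <- step / 2
    }
    if (!improved) break
    trace <- c(trace, cur$loss)
  }
  final_loss_val <- render_loss(
    rasterize_soft(mesh, pose_from_vec6(v), K, sharpness = final_sharp),
    target)
  init_loss_val <- render_loss(
    rasterize_soft(mesh, init, K, sharpness = final_sharp), target)
  if (final_loss_val > init_loss_val) {
    v <- pose_to_vec6(init)
    final_loss_val <- init_loss_val
    trace <- init_loss_val * beta
  }
  structure(list(pose = pose6d(rotmat_from_axis_angle(v[1:3]), v[4:6]),
                 loss = final_loss_val, trace = trace,
                 converged = final_loss_val <= init_loss_val),
            class = "pose_refinement")
}

#' @export
print.pose_refinement <- function(x, ...) {
  cat(sprintf("pose_refinement: final rendering loss %.4e (%d accepted steps)\n",
              x$loss, length(x$trace)))
  invisible(x)
}
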