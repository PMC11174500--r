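#' ADD: average 3D distance of model points
#'
#' Mean distance between model points transformed by the predicted and the
#' ground-truth pose: `mean_i ||(R x_i + t) - (Rbar x_i + tbar)||`. A pose
#' is conventionally counted correct when ADD is below 10% of the model
#' diameter.
#'
#' @param model_points N x 3 model points (mesh vertices or a fixed
#'   subsample), or a `feature_points3d`.
#' @param pred,gt Predicted and ground-truth `pose6d`.
#' @return Mean distance in model units.
#' @export
add_metric <- function(model_points, pred, gt) {
  if (inherits(model_points, "feature_points3d")) model_points <- model_points$points
  model_points <- as_points3(model_points)
  if (nrow(model_points) < 1) stop("empty model point set")
  mean(sqrt(rowSums((pose_apply(pred, model_points) -
                       pose_apply(gt, model_points))^2)))
}

#' ADD-S: symmetric-object variant of ADD
#'
#' Pairs every predicted-pose point with its nearest ground-truth-pose point
#' instead of its own counterpart:
#' `mean_i min_j ||(R x_i + t) - (Rbar x_j + tbar)||`. Always `<=` ADD;
#' equals 0 when the prediction differs from the truth by an exact symmetry
#' of the point set.
#'
#' @inheritParams add_metric
#' @return Mean nearest-point distance in model units.
#' @export
add_s_metric <- function(model_points, pred, gt) {
  if (inherits(model_points, "feature_points3d")) model_points <- model_points$points
  model_points <- as_points3(model_points)
  if (nrow(model_points) < 1) stop("empty model point set")
  a <- pose_apply(pred, model_points)
  b <- pose_apply(gt, model_points)
  mean(.cpp_nn_dists(a, b))
}

#' 2D projection error
#'
#' Mean pixel distance between the projections of the feature points under
#' the predicted and the ground-truth pose. Averaged over the implicit
#' keypoints by default (any point set can be passed). Points behind the
#' camera under either pose are flagged: the sample's error is `NA` and a
#' warning states the policy.
#'
#' @param keypoints M x 3 model points or `feature_points3d`.
#' @param pred,gt Predicted and ground-truth `pose6d`.
#' @param K A `camera_intrinsics`.
#' @return Mean projection distance in pixels (`NA` if any point is behind
#'   the camera).
#' @export
projection_error_2d <- function(keypoints, pred, gt, K) {
  if (inherits(keypoints, "feature_points3d")) keypoints <- keypoints$points
  keypoints <- as_points3(keypoints)
  if (nrow(keypoints) < 1) stop("empty keypoint set")
  pp <- project_points(keypoints, pred, K)
  pg <- project_points(keypoints, gt, K)
  if (any(pp$depth <= 0) || any(pg$depth <= 0)) {
    warning("point behind camera under a pose; sample flagged NA")
    return(NA_real_)
  }
  mean(sqrt(rowSums((pp$uv - pg$uv)^2)))
}

#' Intersection over union of two binary masks
#'
#' `|A intersect B| / |A union B|`. Two empty masks are defined as IOU 0
#' (with a warning).
#'
#' @param a,b Binary masks of identical shape.
#' @return IOU in `[0, 1]`.
#' @export
iou <- function(a, b) {
  if (!all(dim(a) == dim(b))) stop("mask shapes differ")
  av <- as.integer(a) == 1L
  bv <- as.integer(b) == 1L
  uni <- sum(av | bv)
  if (uni == 0) {
    warning("both masks empty; IOU defined as 0")
    return(0)
  }
  sum(av & bv) / uni
}

#' Evaluate predicted poses against ground truth
#'
#' Computes the full metric suite over a set of pose pairs: per-sample ADD
#' (or ADD-S when the instrument is flagged symmetric), 2D projection error
#' over the implicit keypoints, optional IOU between the reprojected hard
#' mask and a reference mask, and the threshold accuracies
#' `ADD(S) < 0.1 d`, `2D error < 5 px` and `< 3 px`. When ground-truth poses
#' are missing entirely, only IOU against the provided masks is reported
#' (the protocol for real footage without pose labels).
#'
#' @param pred List of predicted `pose6d` (entries may be `NULL` for failed
#'   samples, which count as incorrect).
#' @param gt Optional list of ground-truth `pose6d` (same length).
#' @param mesh The instrument `tri_mesh`.
#' @param K A `camera_intrinsics`.
#' @param keypoints `feature_points3d` used for the 2D projection error;
#'   default: 8 farthest-point-sampled vertices.
#' @param masks Optional list of observed binary masks for the IOU column.
#' @param symmetric Use ADD-S instead of ADD for the 0.1 d accuracy?
#' @param add_threshold Fraction of the mesh diameter (default 0.1).
#' @param px_thresholds 2D-error thresholds in px (default `c(5, 3)`).
#' @param max_model_points Vertex budget for ADD; larger meshes are
#'   subsampled deterministically (count reported).
#' @param instrument_id Label for the report.
#' @return An `eval_report`: list with `per_sample` (data.frame) and
#'   `summary` (accuracies in percent, mean IOU, thresholds, counts).
#' @export
evaluate_poses <- function(pred, gt = NULL, mesh, K,
                           keypoints = NULL, masks = NULL,
                           symmetric = FALSE, add_threshold = 0.1,
                           px_thresholds = c(5, 3),
                           max_model_points = 10000L,
                           instrument_id = "instrument") {
  n <- length(pred)
  if (is.null(keypoints)) keypoints <- farthest_point_sampling(mesh, 8L)
  mp <- mesh$vertices
  if (nrow(mp) > max_model_points) {
    old <- local_seed(20231L)
    mp <- mp[sample.int(nrow(mp), max_model_points), , drop = FALSE]
    restore_seed(old)
  }
  diam <- mesh_diameter(mesh)

  iou_col <- rep(NA_real_, n)
  if (!is.null(masks)) {
    for (i in seq_len(n)) {
      if (is.null(pred[[i]]) || is.null(masks[[i]])) next
      reproj <- suppressWarnings(rasterize_hard(mesh, pred[[i]], K))
      iou_col[i] <- iou(reproj, masks[[i]])
    }
  }

  if (is.null(gt)) {
    per <- data.frame(sample = seq_len(n), iou = iou_col)
    summary <- list(instrument_id = instrument_id, n = n,
                    symmetric = symmetric, mode = "iou_only",
                    mean_iou = mean(iou_col, na.rm = TRUE))
    return(structure(list(per_sample = per, summary = summary),
                     class = "eval_report"))
  }
  stopifnot(length(gt) == n)

  add_col <- adds_col <- px_col <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    if (is.null(pred[[i]]) || is.null(gt[[i]])) next
    add_col[i] <- add_metric(mp, pred[[i]], gt[[i]])
    adds_col[i] <- add_s_metric(mp, pred[[i]], gt[[i]])
    px_col[i] <- suppressWarnings(
      projection_error_2d(keypoints, pred[[i]], gt[[i]], K))
  }
  add_used <- if (symmetric) adds_col else add_col
  ok_add <- !is.na(add_used) & add_used < add_threshold * diam
  acc_px <- vapply(px_thresholds, function(th) {
    100 * sum(!is.na(px_col) & px_col < th) / n
  }, 0.0)
  per <- data.frame(sample = seq_len(n), add = add_col, add_s = adds_col,
                    px_err = px_col, iou = iou_col)
  summary <- list(
    instrument_id = instrument_id, n = n, symmetric = symmetric,
    mode = "full",
    model_points = nrow(mp), diameter = diam,
    add_threshold = add_threshold * diam,
    acc_add = 100 * sum(ok_add) / n,
    acc_px = setNames(acc_px, paste0("px", px_thresholds)),
    px_thresholds = px_thresholds,
    mean_iou = if (all(is.na(iou_col))) NA_real_ else mean(iou_col, na.rm = TRUE)
  )
  structure(list(per_sample = per, summary = summary), class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  s <- x$summary
  cat(sprintf("eval_report: %s, n = %d (%s, %s)\n", s$instrument_id, s$n,
              if (isTRUE(s$symmetric)) "ADD-S" else "ADD", s$mode))
  if (identical(s$mode, "full")) {
    cat(sprintf("  ADD(S)(0.1 d): %.2f%%\n", s$acc_add))
    for (k in seq_along(s$px_thresholds)) {
      cat(sprintf("  2D proj (%g px): %.2f%%\n", s$px_thresholds[k],
                  s$acc_px[k]))
    }
  }
  if (!is.null(s$mean_iou) && !is.na(s$mean_iou)) {
    cat(sprintf("  mean IOU: %.4f\n", s$mean_iou))
  }
  invisible(x)
}

#' Write an evaluation report
#'
#' Serializes an `eval_report` as JSON (summary + per-sample table) and a
#' CSV mirror of the per-sample metrics.
#'
#' @param report An `eval_report`.
#' @param json_path,csv_path Output paths (either may be `NULL`).
#' @return `report`, invisibly.
#' @export
write_eval_report <- function(report, json_path = NULL, csv_path = NULL) {
  if (!is.null(json_path)) {
    jsonlite::write_json(list(summary = report$summary,
                              per_sample = report$per_sample),
                         json_path, auto_unbox = TRUE, digits = NA,
                         na = "null")
  }
  if (!is.null(csv_path)) {
    write.csv(report$per_sample, csv_path, row.names = FALSE)
  }
  invisible(report)
}
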