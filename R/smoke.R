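#' Scaled-down end-to-end smoke study
#'
#' The package's canonical desk-scale experiment: generate a 200-sample
#' silhouette dataset of the toy hook instrument (128x96 masks, 135 px
#' focal length so the object always stays in frame under the default pose
#' ranges; no noise augmentation, whose absolute pixel magnitudes are
#' calibrated for 640x480 masks and would erase a 2-px-wide silhouette at
#' this resolution), train the width-0.25 network for 30 epochs with the
#' staged schedule scaled proportionally (12/16/2, Adam 2e-3 stepped to
#' 5e-4), and evaluate on training samples: heatmap-loss drop from epoch 0,
#' mean keypoint error, and mean IOU of the full inference pipeline
#' (PnP + contour disambiguation + silhouette refinement).
#'
#' Everything is seeded; the same seed reproduces the dataset, the
#' parameter trajectory and the metrics exactly.
#'
#' @param out_dir Directory for the generated dataset.
#' @param seed Integer seed.
#' @param n Dataset size.
#' @param epochs Training epochs.
#' @param eval_n Training samples used for the keypoint/IOU evaluation.
#' @param refine_iters Refinement iteration cap per sharpness level.
#' @param verbose Print per-epoch training lines?
#' @return List with `checkpoint`, `manifest`, and `metrics` (named list:
#'   `heatmap_loss_drop`, `keypoint_err_hm_px`, `mean_iou`, `n_ok`).
#' @export
smoke_study <- function(out_dir, seed = 1L, n = 200L, epochs = 30L,
                        eval_n = 20L, refine_iters = 40L, verbose = FALSE) {
  mesh <- toy_instrument("hook")
  K <- camera_intrinsics(135, 135, 64, 48, 128L, 96L)
  manifest <- generate_dataset(mesh, K, default_pose_ranges(mesh), n = n,
                               seed = seed, out_dir = out_dir, noise = NULL)
  manifest$mesh <- mesh
  config <- network_config(width_mult = 0.25, input_size = c(128L, 96L),
                           block_convs = 1L, head_channels = 32L)
  schedule <- train_schedule(
    total_epochs = as.integer(epochs),
    stage_epochs = smoke_stage_split(epochs),
    lr_epochs = as.integer(c(0L, round(0.9 * epochs))),
    lr_values = c(2e-3, 5e-4))
  ck <- train_network(manifest, config, schedule, seed = seed,
                      batch_size = 8L, verbose = verbose)
  errs <- c(); ious <- c(); n_ok <- 0L
  for (i in seq_len(min(eval_n, n))) {
    s <- load_sample(manifest, i)
    hm <- backbone_forward(s$mask, config, ck$params)
    pr <- regress_coordinates(hm, tau = config$tau, stride = config$stride)
    v <- s$visible & pr$visible
    errs <- c(errs, sqrt(rowSums((pr$uv[v, , drop = FALSE] -
                                    s$uv[v, , drop = FALSE])^2)))
    est <- suppressWarnings(infer_pose(s$mask, ck, mesh, K, refine = TRUE,
                                       refine_iters = refine_iters))
    if (est$ok) { n_ok <- n_ok + 1L; ious <- c(ious, est$iou) }
  }
  metrics <- list(
    heatmap_loss_drop = ck$log$heatmap_loss[1] / tail(ck$log$heatmap_loss, 1),
    keypoint_err_hm_px = mean(errs) / config$stride,
    mean_iou = mean(ious),
    n_ok = n_ok
  )
  list(checkpoint = ck, manifest = manifest, metrics = metrics)
}

# 30 -> c(12, 16, 2): proportional to the full 50/70/10 recipe
smoke_stage_split <- function(epochs) {
  base <- c(50L, 70L, 10L)
  st <- pmax(1L, floor(base * epochs / 130))
  st[1] <- st[1] + (as.integer(epochs) - sum(st))
  st
}
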