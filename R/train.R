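#' Training schedule
#'
#' Staged training: the first stage uses only the heatmap loss, the second
#' adds the reprojection loss of the implicit keypoints (through the BPnP
#' layer), and the final stage the full composite objective including the
#' silhouette rendering loss. Defaults follow the published recipe: 130
#' epochs split 50 / 70 / 10, learning rate 2e-5 stepped to 5e-6 (epoch 50),
#' 2e-6 (epoch 100) and 2e-7 (epoch 120), Adam with beta1 = 0.9 and weight
#' decay 1e-3.
#'
#' @param total_epochs Total number of epochs.
#' @param stage_epochs Length-3 stage lengths (must sum to `total_epochs`).
#' @param lr_epochs Epochs (0-based) at which the learning rate changes.
#' @param lr_values Learning rates taking effect at `lr_epochs`.
#' @param beta1,beta2 Adam moment coefficients.
#' @param weight_decay L2 weight decay coefficient.
#' @return A `train_schedule` object.
#' @export
train_schedule <- function(total_epochs = 130L,
                           stage_epochs = c(50L, 70L, 10L),
                           lr_epochs = c(0L, 50L, 100L, 120L),
                           lr_values = c(2e-5, 5e-6, 2e-6, 2e-7),
                           beta1 = 0.9, beta2 = 0.999,
                           weight_decay = 1e-3) {
  stopifnot(sum(stage_epochs) == total_epochs,
            length(lr_epochs) == length(lr_values))
  structure(list(total_epochs = as.integer(total_epochs),
                 stage_epochs = as.integer(stage_epochs),
                 lr_epochs = as.integer(lr_epochs),
                 lr_values = lr_values,
                 beta1 = beta1, beta2 = beta2,
                 weight_decay = weight_decay),
            class = "train_schedule")
}

#' Proportionally scaled schedule
#'
#' Rescales the stage boundaries and learning-rate steps of a schedule to a
#' different epoch budget (for scaled-down runs); the base learning rate can
#' be overridden, preserving the relative step ratios.
#'
#' @param total_epochs New epoch budget.
#' @param base A `train_schedule` to scale (default the full recipe).
#' @param base_lr Optional replacement for the initial learning rate.
#' @return A `train_schedule`.
#' @export
scale_schedule <- function(total_epochs, base = train_schedule(),
                           base_lr = NULL) {
  f <- total_epochs / base$total_epochs
  stages <- floor(base$stage_epochs * f)
  stages[1] <- stages[1] + (total_epochs - sum(stages))
  lr_ep <- unique(pmin(floor(base$lr_epochs * f), total_epochs - 1L))
  lr_vals <- base$lr_values[seq_along(lr_ep)]
  if (!is.null(base_lr)) lr_vals <- lr_vals * (base_lr / lr_vals[1])
  train_schedule(total_epochs = total_epochs, stage_epochs = stages,
                 lr_epochs = lr_ep, lr_values = lr_vals,
                 beta1 = base$beta1, beta2 = base$beta2,
                 weight_decay = base$weight_decay)
}

lr_at_epoch <- function(schedule, epoch) {
  # epoch is 0-based
  idx <- max(which(schedule$lr_epochs <= epoch))
  schedule$lr_values[idx]
}

stage_at_epoch <- function(schedule, epoch) {
  b <- cumsum(schedule$stage_epochs)
  if (epoch < b[1]) 1L else if (epoch < b[2]) 2L else 3L
}

adam_new <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0),
       t = 0L)
}

adam_step <- function(params, grads, state, lr, schedule) {
  state$t <- state$t + 1L
  b1 <- schedule$beta1; b2 <- schedule$beta2
  for (nm in names(grads)) {
    # decay only convolution weights: decaying normalization gains and
    # biases actively un-learns the feature scales
    wd <- if (endsWith(nm, ".w")) schedule$weight_decay else 0
    g <- grads[[nm]] + wd * params[[nm]]
    state$m[[nm]] <- b1 * state$m[[nm]] + (1 - b1) * g
    state$v[[nm]] <- b2 * state$v[[nm]] + (1 - b2) * g^2
    mhat <- state$m[[nm]] / (1 - b1^state$t)
    vhat <- state$v[[nm]] / (1 - b2^state$t)
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + 1e-8)
  }
  list(params = params, state = state)
}

#' Train the heatmap network
#'
#' Staged end-to-end training on a generated dataset. Per stage the
#' objective is (1) heatmap MSE against the Gaussian ground truth, (2) plus
#' `alpha` times the reprojection loss of the soft-argmax keypoints, whose
#' gradient flows through the implicit-function-theorem backward pass of
#' the PnP layer, and (3) plus `beta` times the silhouette rendering loss,
#' whose pose gradient is chained through the same backward pass. Updates
#' use Adam with the schedule's learning-rate steps; training aborts with
#' the last finite checkpoint if the loss turns non-finite. Fully seeded:
#' identical seeds give identical parameter trajectories.
#'
#' @param manifest A `pose_manifest` from [generate_dataset()] /
#'   [read_manifest()].
#' @param config A [network_config()] matching the dataset resolution.
#' @param schedule A [train_schedule()].
#' @param seed Integer seed (initialization + shuffling).
#' @param weights [loss_weights()] for stages 2-3.
#' @param lambda Weight of the ground-truth term inside the reprojection
#'   loss.
#' @param params Optional warm-start parameters.
#' @param batch_size Gradients are accumulated over this many samples per
#'   Adam update.
#' @param grad_clip Per-keypoint norm cap on the pose-loss gradient injected
#'   into the soft-argmax coordinates.
#' @param verbose Print a per-epoch summary line?
#' @return A `maskpose_checkpoint`: list with `params`, `config`, `log`
#'   (per-epoch data.frame), `schedule`, `keypoints3d`.
#' @export
train_network <- function(manifest, config, schedule = train_schedule(),
                          seed = 1L, weights = loss_weights(), lambda = 1,
                          params = NULL, batch_size = 1L, grad_clip = 0.01,
                          verbose = TRUE) {
  hd <- manifest$header
  K <- camera_intrinsics(hd$intrinsics$fx, hd$intrinsics$fy,
                         hd$intrinsics$cx, hd$intrinsics$cy,
                         hd$intrinsics$width, hd$intrinsics$height)
  if (!all(config$input_size == c(K$width, K$height))) {
    stop("network input size does not match the dataset resolution")
  }
  z <- hd$keypoints3d
  n <- length(manifest$samples)
  data <- lapply(seq_len(n), function(i) {
    s <- load_sample(manifest, i, noisy = TRUE, heatmaps = TRUE)
    s$clean <- read_mask_png(s$clean_mask_path, "binary")
    s
  })
  if (is.null(params)) params <- init_network(config, seed = sub_seed(seed, 1L))
  state <- adam_new(params)
  pose_cache <- vector("list", n)   # warm starts for the PnP solves
  log <- list()
  last_params <- params

  for (epoch in seq_len(schedule$total_epochs) - 1L) {
    stage <- stage_at_epoch(schedule, epoch)
    lr <- lr_at_epoch(schedule, epoch)
    old <- local_seed(sub_seed(seed, 100L + epoch))
    order_idx <- sample.int(n)
    restore_seed(old)
    ep_lh <- ep_lp <- ep_lr <- 0; n_lp <- 0L
    acc <- NULL; n_acc <- 0L
    for (i in order_idx) {
      s <- data[[i]]
      g <- backbone_graph(s$mask, config, params)
      tp <- g$tape
      hm_id <- g$heatmap_id
      lh_id <- nd_mse(tp, hm_id, as.numeric(s$heatmap))
      seeds <- setNames(list(1), as.character(lh_id))
      ep_lh <- ep_lh + nd_value(tp, lh_id)

      if (stage >= 2L && sum(s$visible) >= 4) {
        co_id <- nd_softargmax(tp, hm_id, tau = config$tau,
                               stride = config$stride)
        x_pred <- nd_value(tp, co_id)
        # warm-started, restart-free solves: early-epoch keypoints are far
        # from any consistent pose and restarts would only burn iterations
        layer <- tryCatch(
          bpnp_layer(x_pred, z, K, visible = s$visible,
                     init = pose_cache[[i]], restart_tol = Inf,
                     max_iter = 60L, grad_tol = 1e-7),
          error = function(e) NULL)
        if (!is.null(layer) && layer$solution$converged) {
          pose_cache[[i]] <- layer$pose
          pb <- pnp_problem(x_pred, z, K, x_star = s$uv, lambda = lambda,
                            visible = s$visible)
          lg <- reprojection_loss_grads(pb, layer$pose)
          dlp_dx <- lg$dx + layer$backward(lg$dpose)
          ep_lp <- ep_lp + lg$loss; n_lp <- n_lp + 1L
          dx_total <- weights$alpha * dlp_dx
          if (stage >= 3L) {
            rl <- render_loss_pose_grad(mesh_for_manifest(manifest),
                                        layer$pose, K, s$clean)
            ep_lr <- ep_lr + rl$loss
            dx_total <- dx_total + weights$beta * layer$backward(rl$grad)
          }
          # cap the per-keypoint gradient injected into the coordinates:
          # near-degenerate PnP Hessians can make the implicit gradient
          # arbitrarily large and one bad sample would erase the heatmaps
          rn <- sqrt(rowSums(dx_total^2))
          over <- which(rn > grad_clip)
          for (r in over) dx_total[r, ] <- dx_total[r, ] * grad_clip / rn[r]
          seeds[[as.character(co_id)]] <- dx_total
        }
      }
      grads <- tape_backward(tp, seeds)
      if (is.null(acc)) {
        acc <- grads
      } else {
        for (nm in names(grads)) {
          acc[[nm]] <- if (is.null(acc[[nm]])) grads[[nm]]
                       else acc[[nm]] + grads[[nm]]
        }
      }
      n_acc <- n_acc + 1L
      if (n_acc >= batch_size || i == order_idx[length(order_idx)]) {
        for (nm in names(acc)) acc[[nm]] <- acc[[nm]] / n_acc
        upd <- adam_step(params, acc, state, lr, schedule)
        params <- upd$params; state <- upd$state
        acc <- NULL; n_acc <- 0L
      }
      if (!all(vapply(params, function(p) all(is.finite(p)), TRUE))) {
        warning("non-finite parameters at epoch ", epoch, "; aborting")
        return(make_checkpoint(last_params, config, do.call(rbind, log),
                               schedule, z))
      }
      last_params <- params
    }
    log[[length(log) + 1]] <- data.frame(
      epoch = epoch, stage = stage, lr = lr,
      heatmap_loss = ep_lh / n,
      reproj_loss = if (n_lp > 0) ep_lp / n_lp else NA_real_,
      render_loss = if (stage >= 3L) ep_lr / max(n_lp, 1L) else NA_real_
    )
    if (verbose) {
      message(sprintf(
        "epoch %3d stage %d lr %.1e  Lh %.3e  Lp %s  Lr %s", epoch, stage,
        lr, ep_lh / n,
        if (n_lp > 0) sprintf("%.3e", ep_lp / n_lp) else "-",
        if (stage >= 3L) sprintf("%.3e", ep_lr / max(n_lp, 1L)) else "-"))
    }
  }
  make_checkpoint(params, config, do.call(rbind, log), schedule, z)
}

make_checkpoint <- function(params, config, log, schedule, keypoints3d) {
  structure(list(params = params, config = config, log = log,
                 schedule = schedule, keypoints3d = keypoints3d),
            class = "maskpose_checkpoint")
}

# instrument mesh used by the rendering stage; cached on the manifest object
mesh_for_manifest <- function(manifest) {
  if (!is.null(manifest$mesh)) return(manifest$mesh)
  stop("manifest carries no mesh; attach one as manifest$mesh for stage-3 training")
}

#' @export
print.maskpose_checkpoint <- function(x, ...) {
  cat(sprintf("maskpose_checkpoint: %d parameter tensors, %d epochs logged\n",
              length(x$params), if (is.null(x$log)) 0L else nrow(x$log)))
  invisible(x)
}

#' Save / load a checkpoint
#'
#' Flat named-parameter archive with the config echoed alongside (RDS
#' serialization).
#'
#' @param checkpoint A `maskpose_checkpoint`.
#' @param path File path.
#' @return `save_checkpoint`: `path` invisibly; `load_checkpoint`: the
#'   checkpoint.
#' @export
save_checkpoint <- function(checkpoint, path) {
  saveRDS(checkpoint, path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  ck <- readRDS(path)
  stopifnot(inherits(ck, "maskpose_checkpoint"))
  ck
}
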