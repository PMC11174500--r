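#' Gaussian ground-truth heatmaps
#'
#' Builds one per-keypoint likelihood map by placing an impulse at each
#' visible keypoint's ground-truth image position and evaluating a Gaussian
#' kernel on the heatmap grid:
#' `map_i(p) = exp(-||p * stride - x*_i||^2 / (2 sigma^2))` (peak value 1).
#' Heatmap grid pixel `p` (0-based) corresponds to image coordinate
#' `p * stride`; invisible keypoints get all-zero maps.
#'
#' @param proj A `projections2d` (or N x 2 uv matrix, all taken visible).
#' @param K A `camera_intrinsics` giving the image resolution.
#' @param sigma Gaussian width in image pixels (default 8).
#' @param stride Image-to-heatmap resolution ratio (default 4; must divide
#'   the image size).
#' @return A `heatmap` object: array `(h, w, N)` with attributes `stride`
#'   and `sigma`.
#' @export
make_heatmap_gt <- function(proj, K, sigma = 8, stride = 4L) {
  stopifnot(sigma > 0)
  uv <- if (inherits(proj, "projections2d")) proj$uv else as.matrix(proj)
  visible <- if (inherits(proj, "projections2d")) proj$visible
             else rep(TRUE, nrow(uv))
  stride <- as.integer(stride)
  if (K$width %% stride != 0 || K$height %% stride != 0) {
    stop("stride must divide the image size")
  }
  h <- K$height %/% stride
  w <- K$width %/% stride
  n <- nrow(uv)
  gu <- (seq_len(w) - 1) * stride
  gv <- (seq_len(h) - 1) * stride
  maps <- array(0, c(h, w, n))
  for (i in seq_len(n)) {
    if (!visible[i] || is.na(uv[i, 1])) next
    du2 <- (gu - uv[i, 1])^2
    dv2 <- (gv - uv[i, 2])^2
    maps[, , i] <- exp(-(outer(dv2, du2, "+")) / (2 * sigma^2))
  }
  structure(maps, stride = stride, sigma = sigma,
            class = c("heatmap", "array"))
}

#' Soft-argmax coordinate regression
#'
#' Differentiable extraction of keypoint image coordinates from heatmaps:
#' each map is turned into a spatial distribution by
#' `softmax(tau * map)` and the keypoint is its expected grid position,
#' scaled by the heatmap stride. All-zero maps are flagged invisible.
#'
#' The temperature trades off sharpness against sub-pixel accuracy: too low
#' lets the background pull the estimate toward the image center, too high
#' collapses onto the nearest grid cell (quantizing to `stride/2` px). The
#' default (25) recovers Gaussian ground-truth peaks to well under 0.5 px
#' while keeping the background weight negligible.
#'
#' @param heatmap A `heatmap` array `(h, w, N)` (raw non-negative maps).
#' @param tau Softmax temperature (default 25).
#' @param stride Image-to-heatmap ratio; defaults to the heatmap attribute.
#' @return A `projections2d` with continuous image-pixel coordinates.
#' @export
regress_coordinates <- function(heatmap, tau = 25, stride = NULL) {
  stride <- stride %||% attr(heatmap, "stride") %||% 1L
  d <- dim(heatmap)
  h <- d[1]; w <- d[2]; n <- if (length(d) == 3) d[3] else 1L
  maps <- array(heatmap, c(h, w, n))
  gu <- (seq_len(w) - 1) * stride
  gv <- (seq_len(h) - 1) * stride
  uv <- matrix(NA_real_, n, 2)
  visible <- rep(FALSE, n)
  for (i in seq_len(n)) {
    m <- maps[, , i]
    if (all(m == 0)) next
    e <- exp(tau * (m - max(m)))
    e <- e / sum(e)
    uv[i, ] <- c(sum(colSums(e) * gu), sum(rowSums(e) * gv))
    visible[i] <- TRUE
  }
  structure(list(uv = uv, visible = visible, depth = rep(NA_real_, n)),
            class = "projections2d")
}

#' Heatmap loss
#'
#' Mean squared error between predicted and ground-truth heatmap stacks
#' (over all maps and grid cells); the first-stage supervision of the
#' keypoint network.
#'
#' @param m,m_star Heatmap arrays of identical shape.
#' @return Scalar MSE.
#' @export
heatmap_loss <- function(m, m_star) {
  if (!all(dim(m) == dim(m_star))) stop("heatmap shapes differ")
  mean((as.numeric(m) - as.numeric(m_star))^2)
}

#' Composite training loss
#'
#' `l_final = l_h + alpha * l_p + beta * l_r`: heatmap MSE plus weighted
#' reprojection loss and weighted silhouette rendering loss.
#'
#' @param lh,lp,lr Scalar component losses (heatmap, reprojection,
#'   rendering).
#' @param weights A [loss_weights()] object.
#' @return Scalar weighted sum.
#' @examples
#' final_loss(1, 2, 3, loss_weights())  # 1 + 0.00005*2 + 1.2*3 = 4.7001
#' @export
final_loss <- function(lh, lp, lr, weights = loss_weights()) {
  stopifnot(is.finite(lh), is.finite(lp), is.finite(lr))
  lh + weights$alpha * lp + weights$beta * lr
}

#' Loss weights
#'
#' Weights of the composite objective; defaults are alpha = 0.00005 on the
#' reprojection term and beta = 1.2 on the rendering term.
#'
#' @param alpha Non-negative weight of the reprojection loss.
#' @param beta Non-negative weight of the rendering loss.
#' @return A `loss_weights` list.
#' @export
loss_weights <- function(alpha = 0.00005, beta = 1.2) {
  stopifnot(alpha >= 0, beta >= 0)
  structure(list(alpha = alpha, beta = beta), class = "loss_weights")
}
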