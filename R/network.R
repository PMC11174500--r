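#' Heatmap network configuration
#'
#' A compact multi-resolution backbone in the high-resolution-network
#' family: a stride-4 stem, four cascaded stages that progressively add
#' parallel branches at strides 8, 16 and 32 (each new branch at half the
#' lowest resolution of the previous stage, with doubled channel width),
#' all-to-all fusion (identity / strided 3x3 convs down / 1x1 conv +
#' nearest upsampling up) after every stage, channel-space tensor
#' self-attention (CSTSA) on the fused finest branch after stage 3, and a
#' head emitting one heatmap per keypoint at the finest (stride 4)
#' resolution.
#'
#' @param widths Channels of the four branches at full width (doubling as
#'   resolution halves).
#' @param width_mult Multiplier scaling all widths (e.g. 0.25 for the tiny
#'   test model).
#' @param n_keypoints Number of output heatmaps.
#' @param stride Heatmap stride (fixed by the finest branch; 4).
#' @param attention Include the CSTSA block?
#' @param input_size Image size `c(width, height)`; inputs of any other size
#'   are rejected (no silent resizing).
#' @param softmax_output Normalize each output map by a spatial softmax?
#'   Off by default: the Gaussian targets of the MSE are not distributions;
#'   the soft-argmax applies its own softmax.
#' @param tau Soft-argmax temperature used at inference/training.
#' @return A `network_config` object.
#' @export
network_config <- function(widths = c(32, 64, 128, 256), width_mult = 1,
                           n_keypoints = 8L, stride = 4L, attention = TRUE,
                           input_size = c(640L, 480L),
                           softmax_output = FALSE, tau = 25,
                           head_channels = NULL, block_convs = 2L) {
  w <- pmax(1L, as.integer(round(widths * width_mult)))
  stopifnot(stride == 4L, length(w) == 4)
  if (any(input_size %% 32 != 0)) {
    stop("input size must be divisible by 32 (coarsest branch)")
  }
  if (is.null(head_channels)) head_channels <- 4L * w[1]
  structure(list(widths = w, n_keypoints = as.integer(n_keypoints),
                 stride = 4L, attention = isTRUE(attention),
                 input_size = as.integer(input_size),
                 softmax_output = isTRUE(softmax_output), tau = tau,
                 head_channels = as.integer(head_channels),
                 block_convs = max(1L, as.integer(block_convs))),
            class = "network_config")
}

# parameter specification: list of name -> dim for conv weights/biases
network_param_spec <- function(config) {
  w <- config$widths
  spec <- list()
  addc <- function(name, kh, kw, cin, cout, norm = FALSE) {
    spec[[paste0(name, ".w")]] <<- c(kh, kw, cin, cout)
    spec[[paste0(name, ".b")]] <<- cout
    if (norm) {
      spec[[paste0("norm.", name, ".g")]] <<- cout
      spec[[paste0("norm.", name, ".b")]] <<- cout
    }
  }
  nb <- config$block_convs
  addb <- function(name, width) {
    for (r in seq_len(nb)) addc(sprintf("%s.c%d", name, r), 3, 3, width,
                                width, norm = TRUE)
  }
  addc("stem1", 3, 3, 1, w[1], norm = TRUE)
  addc("stem2", 3, 3, w[1], w[1], norm = TRUE)
  addb("s1.b1", w[1])
  addc("t2", 3, 3, w[1], w[2], norm = TRUE)
  addb("s2.b1", w[1])
  addb("s2.b2", w[2])
  # all-to-all fusion after stage 2 (2 branches)
  addc("f2.12", 3, 3, w[1], w[2])   # down
  addc("f2.21", 1, 1, w[2], w[1])   # up
  addc("t3", 3, 3, w[2], w[3], norm = TRUE)
  addb("s3.b1", w[1])
  addb("s3.b2", w[2])
  addb("s3.b3", w[3])
  for (i in 1:3) for (j in 1:3) {
    if (i == j) next
    k <- if (i < j) 3 else 1
    addc(sprintf("f3.%d%d", i, j), k, k, w[i], w[j])
  }
  if (config$attention) {
    addc("att.u", 1, 1, w[1], w[1])
    addc("att.v", 1, 1, w[1], w[1])
    addc("att.sp", 1, 1, w[1], 1)
  }
  addc("t4", 3, 3, w[3], w[4], norm = TRUE)
  addb("s4.b1", w[1])
  addb("s4.b2", w[2])
  addb("s4.b3", w[3])
  addb("s4.b4", w[4])
  # final fusion feeds only the finest branch (the head's input); fusing
  # into coarser branches after the last stage would train dead parameters
  for (i in 2:4) addc(sprintf("f4.%d1", i), 1, 1, w[i], w[1])
  addc("head1", 3, 3, w[1], config$head_channels, norm = TRUE)
  addc("head2", 1, 1, config$head_channels, config$n_keypoints)
  spec
}

#' Initialize network parameters
#'
#' He-normal initialization of all convolution weights, zero biases;
#' deterministic for a fixed seed.
#'
#' @param config A [network_config()].
#' @param seed Integer seed.
#' @return Named list of parameter arrays.
#' @export
init_network <- function(config, seed = 1L) {
  spec <- network_param_spec(config)
  old <- local_seed(seed)
  on.exit(restore_seed(old))
  params <- list()
  for (name in names(spec)) {
    d <- spec[[name]]
    if (length(d) == 1) {
      params[[name]] <- if (endsWith(name, ".g")) rep(1, d) else numeric(d)
    } else if (name == "head2.w") {
      # zero-init output conv: predictions start at the empty heatmap, so
      # early training shapes the blobs instead of unlearning noise
      params[[name]] <- array(0, d)
    } else {
      fan_in <- prod(d[1:3])
      params[[name]] <- array(rnorm(prod(d), 0, sqrt(2 / fan_in)), d)
    }
  }
  params
}

# build the forward graph on a tape; returns list(tape, heatmap_id, pids)
backbone_graph <- function(mask, config, params) {
  d <- dim(mask)
  if (d[1] != config$input_size[2] || d[2] != config$input_size[1]) {
    stop(sprintf("input must be %dx%d (width x height), got %dx%d",
                 config$input_size[1], config$input_size[2], d[2], d[1]))
  }
  tp <- tape_new()
  pid <- list()
  for (name in names(params)) pid[[name]] <- nd_param(tp, params[[name]], name)
  conv <- function(x, name, stride = 1L, pad = 1L, relu = TRUE) {
    y <- nd_conv2d(tp, x, pid[[paste0(name, ".w")]], pid[[paste0(name, ".b")]],
                   stride = stride, pad = pad)
    gn <- paste0("norm.", name, ".g")
    if (!is.null(pid[[gn]])) {
      y <- nd_instnorm(tp, y, pid[[gn]], pid[[paste0("norm.", name, ".b")]])
    }
    if (relu) nd_relu(tp, y) else y
  }
  block <- function(x, name) {
    for (r in seq_len(config$block_convs)) {
      x <- conv(x, sprintf("%s.c%d", name, r))
    }
    x
  }
  x <- nd_input(tp, array(as.numeric(mask), c(d[1], d[2], 1)))
  # stem to stride 4
  b1 <- conv(x, "stem1", stride = 2L)
  b1 <- conv(b1, "stem2", stride = 2L)
  # stage 1
  b1 <- block(b1, "s1.b1")
  # stage 2: add stride-8 branch, blocks, all-to-all fusion
  b2 <- conv(b1, "t2", stride = 2L)
  b1 <- block(b1, "s2.b1")
  b2 <- block(b2, "s2.b2")
  f1 <- nd_add(tp, c(b1, nd_upsample(tp, conv(b2, "f2.21", pad = 0L,
                                              relu = FALSE), 2L)))
  f2 <- nd_add(tp, c(b2, conv(b1, "f2.12", stride = 2L, relu = FALSE)))
  b1 <- nd_relu(tp, f1); b2 <- nd_relu(tp, f2)
  # stage 3: add stride-16 branch
  b3 <- conv(b2, "t3", stride = 2L)
  b1 <- block(b1, "s3.b1"); b2 <- block(b2, "s3.b2"); b3 <- block(b3, "s3.b3")
  br <- list(b1, b2, b3)
  fused <- vector("list", 3)
  for (j in 1:3) {
    terms <- br[[j]]
    for (i in 1:3) {
      if (i == j) next
      nm <- sprintf("f3.%d%d", i, j)
      t_ <- if (i < j) conv(br[[i]], nm, stride = 2L^(j - i), relu = FALSE)
            else nd_upsample(tp, conv(br[[i]], nm, pad = 0L, relu = FALSE),
                             2L^(i - j))
      terms <- c(terms, t_)
    }
    fused[[j]] <- nd_relu(tp, nd_add(tp, terms))
  }
  b1 <- fused[[1]]; b2 <- fused[[2]]; b3 <- fused[[3]]
  # channel-space tensor self-attention on the fused finest branch
  if (config$attention) b1 <- cstsa_graph(tp, b1, pid)
  # stage 4: add stride-32 branch
  b4 <- conv(b3, "t4", stride = 2L)
  b1 <- block(b1, "s4.b1"); b2 <- block(b2, "s4.b2")
  b3 <- block(b3, "s4.b3"); b4 <- block(b4, "s4.b4")
  br <- list(b1, b2, b3, b4)
  terms <- br[[1]]
  for (i in 2:4) {
    nm <- sprintf("f4.%d1", i)
    terms <- c(terms,
               nd_upsample(tp, conv(br[[i]], nm, pad = 0L, relu = FALSE),
                           2L^(i - 1)))
  }
  fused1 <- nd_relu(tp, nd_add(tp, terms))
  # head on the finest branch
  h <- conv(fused1, "head1")
  h <- conv(h, "head2", pad = 0L, relu = FALSE)
  if (config$softmax_output) h <- nd_softmax_hw(tp, h)
  list(tape = tp, heatmap_id = h, pids = pid)
}

# CSTSA: three parallel attention maps - channel attention along each of the
# two channel-spatial planes (descriptors pooled over the other spatial
# axis, channel softmax, multiplicative reweighting) and a spatial-only
# attention (1x1-conv channel pooling, spatial softmax rescaled to mean 1) -
# combined with a residual connection. A constant input field yields uniform
# attention, i.e. output proportional to input.
cstsa_graph <- function(tp, x_id, pid) {
  d <- dim(nd_value(tp, x_id))
  convp <- function(x, name) {
    nd_conv2d(tp, x, pid[[paste0(name, ".w")]], pid[[paste0(name, ".b")]],
              stride = 1L, pad = 0L)
  }
  # channel-U: pool over w -> (h, 1, c) plane, transform, softmax along h
  u <- nd_mean_axis(tp, x_id, 2L)
  u <- nd_softmax_axis(tp, convp(u, "att.u"), 1L)
  u <- nd_scale(tp, u, d[1])           # uniform attention == 1
  yu <- nd_mul_bcast(tp, x_id, u)
  # channel-V: pool over h -> (1, w, c) plane, softmax along w
  v <- nd_mean_axis(tp, x_id, 1L)
  v <- nd_softmax_axis(tp, convp(v, "att.v"), 2L)
  v <- nd_scale(tp, v, d[2])
  yv <- nd_mul_bcast(tp, x_id, v)
  # space-only: 1x1 conv to one channel, spatial softmax
  sp <- convp(x_id, "att.sp")
  sp <- nd_softmax_hw(tp, sp)
  sp <- nd_scale(tp, sp, d[1] * d[2])
  ysp <- nd_mul_bcast(tp, x_id, sp)
  att <- nd_scale(tp, nd_add(tp, c(yu, yv, ysp)), 1 / 3)
  nd_add(tp, c(x_id, att))
}

#' Backbone forward pass
#'
#' Runs the multi-resolution heatmap network on a binary mask image and
#' returns the predicted heatmaps (stride-4 resolution, one map per
#' keypoint). Inputs of the wrong size raise an error - no silent resizing.
#'
#' @param mask A `mask_image` (or matrix) of size `input_size`.
#' @param config A [network_config()].
#' @param params Parameters from [init_network()] or a trained checkpoint.
#' @param softmax Override the config's spatial-softmax output setting.
#' @return A `heatmap` array `(h, w, N)`.
#' @export
backbone_forward <- function(mask, config, params, softmax = NULL) {
  cfg <- config
  if (!is.null(softmax)) cfg$softmax_output <- isTRUE(softmax)
  g <- backbone_graph(mask, cfg, params)
  structure(nd_value(g$tape, g$heatmap_id),
            stride = cfg$stride, sigma = NA_real_,
            class = c("heatmap", "array"))
}

#' Channel-space tensor self-attention (standalone)
#'
#' Applies the CSTSA block to a feature tensor; exposed mainly for
#' inspection and ablation. Output shape equals input shape.
#'
#' @param features An `(h, w, c)` feature array.
#' @param params Parameter list containing the `att.*` entries (see
#'   [init_network()]); defaults to fresh ones for the given channel count.
#' @param seed Seed for default parameter creation.
#' @return An `(h, w, c)` array.
#' @export
cstsa_attention <- function(features, params = NULL, seed = 1L) {
  d <- dim(features)
  if (is.null(params)) {
    old <- local_seed(seed)
    on.exit(restore_seed(old))
    params <- list(
      "att.u.w" = array(rnorm(d[3]^2, 0, sqrt(2 / d[3])), c(1, 1, d[3], d[3])),
      "att.u.b" = numeric(d[3]),
      "att.v.w" = array(rnorm(d[3]^2, 0, sqrt(2 / d[3])), c(1, 1, d[3], d[3])),
      "att.v.b" = numeric(d[3]),
      "att.sp.w" = array(rnorm(d[3], 0, sqrt(2 / d[3])), c(1, 1, d[3], 1)),
      "att.sp.b" = numeric(1)
    )
  }
  tp <- tape_new()
  pid <- list()
  for (name in names(params)) pid[[name]] <- nd_param(tp, params[[name]], name)
  x <- nd_input(tp, features)
  out <- cstsa_graph(tp, x, pid)
  nd_value(tp, out)
}
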