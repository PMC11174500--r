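# Minimal reverse-mode automatic differentiation over (H, W, C) arrays,
# sufficient for the heatmap backbone: convolution (via compiled
# im2col/col2im + BLAS GEMM), ReLU, addition, nearest-neighbour upsampling,
# softmax over spatial or channel axes, broadcast multiplication, spatial
# soft-argmax and MSE. Nodes are stored on a tape (environment) and
# gradients are accumulated in reverse topological (= insertion) order.

tape_new <- function() {
  tp <- new.env(parent = emptyenv())
  tp$nodes <- list()
  tp
}

tp_add_node <- function(tp, value, parents = integer(0), vjp = NULL,
                        cache = NULL, param = NULL) {
  id <- length(tp$nodes) + 1L
  tp$nodes[[id]] <- list(value = value, parents = parents, vjp = vjp,
                         cache = cache, param = param)
  id
}

nd_value <- function(tp, id) {
  # force id before touching tp$nodes: the id argument may be an unevaluated
  # expression that itself appends nodes to the tape
  id <- as.integer(id)
  tp$nodes[[id]]$value
}

# leaf holding an input (no gradient tracked beyond naming)
nd_input <- function(tp, x) tp_add_node(tp, x)

# leaf holding a named parameter; gradients are collected under this name
nd_param <- function(tp, x, name) tp_add_node(tp, x, param = name)

nd_conv2d <- function(tp, x_id, w_id, b_id, stride = 1L, pad = 1L) {
  x <- nd_value(tp, x_id)
  w <- nd_value(tp, w_id)
  b <- nd_value(tp, b_id)
  d <- dim(x); H <- d[1]; W <- d[2]; C <- d[3]
  dw <- dim(w); kh <- dw[1]; kw <- dw[2]; cin <- dw[3]; cout <- dw[4]
  stopifnot(cin == C)
  col <- .cpp_im2col(as.numeric(x), H, W, C, kh, kw, stride, pad)
  wmat <- matrix(w, kh * kw * cin, cout)   # column-major flatten
  oH <- (H + 2L * pad - kh) %/% stride + 1L
  oW <- (W + 2L * pad - kw) %/% stride + 1L
  y <- crossprod(col, wmat)                # (oH*oW) x cout
  y <- y + rep(b, each = oH * oW)
  yarr <- array(y, c(oH, oW, cout))
  vjp <- function(grad, node) {
    gm <- matrix(grad, oH * oW, cout)
    dw_ <- array(node$cache$col %*% gm, c(kh, kw, cin, cout))
    db_ <- colSums(gm)
    dcol <- tcrossprod(node$cache$wmat, gm)  # (khkwcin) x (oH*oW)
    dx_ <- .cpp_col2im(dcol, H, W, C, kh, kw, stride, pad)
    list(dx_, dw_, db_)
  }
  tp_add_node(tp, yarr, parents = c(x_id, w_id, b_id), vjp = vjp,
              cache = list(col = col, wmat = wmat))
}

nd_relu <- function(tp, x_id) {
  x <- nd_value(tp, x_id)
  y <- pmax(x, 0)
  vjp <- function(grad, node) list(grad * (node$cache$mask))
  tp_add_node(tp, y, parents = x_id, vjp = vjp,
              cache = list(mask = (x > 0) * 1))
}

nd_add <- function(tp, ids) {
  vals <- lapply(ids, nd_value, tp = tp)
  y <- Reduce(`+`, vals)
  vjp <- function(grad, node) rep(list(grad), length(node$parents))
  tp_add_node(tp, y, parents = as.integer(ids), vjp = vjp)
}

nd_upsample <- function(tp, x_id, factor) {
  x <- nd_value(tp, x_id)
  d <- dim(x)
  ih <- rep(seq_len(d[1]), each = factor)
  iw <- rep(seq_len(d[2]), each = factor)
  y <- x[ih, iw, , drop = FALSE]
  vjp <- function(grad, node) {
    f <- node$cache$f; dd <- node$cache$d
    a <- array(grad, c(f, dd[1], f, dd[2], dd[3]))
    s1 <- colSums(a)                     # (d1, f, d2, c)
    s2 <- colSums(aperm(s1, c(2, 1, 3, 4)))  # (d1, d2, c)
    list(s2)
  }
  tp_add_node(tp, y, parents = x_id, vjp = vjp,
              cache = list(f = factor, d = d))
}

# softmax over the spatial axes, per channel (optionally scaled by tau)
nd_softmax_hw <- function(tp, x_id, tau = 1) {
  x <- nd_value(tp, x_id)
  d <- dim(x)
  y <- x
  for (c in seq_len(d[3])) {
    m <- x[, , c]
    e <- exp(tau * (m - max(m)))
    y[, , c] <- e / sum(e)
  }
  vjp <- function(grad, node) {
    p <- node$value; tau <- node$cache$tau; d <- dim(p)
    g <- p
    for (c in seq_len(d[3])) {
      pc <- p[, , c]; gc <- grad[, , c]
      g[, , c] <- tau * pc * (gc - sum(gc * pc))
    }
    list(g)
  }
  tp_add_node(tp, y, parents = x_id, vjp = vjp, cache = list(tau = tau))
}

# softmax along one axis, independently at every other coordinate
nd_softmax_axis <- function(tp, x_id, axis) {
  x <- nd_value(tp, x_id)
  d <- dim(x)
  others <- setdiff(1:3, axis)
  perm <- c(axis, others)
  invperm <- order(perm)
  m <- matrix(aperm(x, perm), d[axis])
  m <- exp(sweep(m, 2, apply(m, 2, max)))
  m <- sweep(m, 2, colSums(m), "/")
  y <- aperm(array(m, d[perm]), invperm)
  vjp <- function(grad, node) {
    d <- node$cache$d; perm <- node$cache$perm; invperm <- node$cache$invperm
    p <- matrix(aperm(node$value, perm), d[perm[1]])
    g <- matrix(aperm(grad, perm), d[perm[1]])
    out <- p * sweep(g, 2, colSums(g * p))
    list(aperm(array(out, d[perm]), invperm))
  }
  tp_add_node(tp, y, parents = x_id, vjp = vjp,
              cache = list(d = d, perm = perm, invperm = invperm))
}

# mean over a single axis, keeping it as a singleton dimension
nd_mean_axis <- function(tp, x_id, axis) {
  x <- nd_value(tp, x_id)
  d <- dim(x)
  y <- apply_keepdim_sum(x, axis) / d[axis]
  vjp <- function(grad, node) {
    d <- node$cache$d; axis <- node$cache$axis
    list(array(rep_broadcast(grad, d), d) / d[axis])
  }
  tp_add_node(tp, y, parents = x_id, vjp = vjp,
              cache = list(d = d, axis = axis))
}

# broadcast a (possibly singleton-dimension) array up to dims d
rep_broadcast <- function(a, d) {
  da <- dim(a)
  ih <- if (da[1] == d[1]) seq_len(d[1]) else rep(1L, d[1])
  iw <- if (da[2] == d[2]) seq_len(d[2]) else rep(1L, d[2])
  ic <- if (da[3] == d[3]) seq_len(d[3]) else rep(1L, d[3])
  a[ih, iw, ic, drop = FALSE]
}

# elementwise product with broadcasting of the second argument
nd_mul_bcast <- function(tp, x_id, a_id) {
  x <- nd_value(tp, x_id)
  a <- nd_value(tp, a_id)
  d <- dim(x)
  ab <- rep_broadcast(a, d)
  y <- x * ab
  vjp <- function(grad, node) {
    d <- dim(node$cache$x); da <- dim(node$cache$a)
    dx_ <- grad * node$cache$ab
    dab <- grad * node$cache$x
    # sum the broadcast axes back down
    for (ax in 1:3) {
      if (da[ax] == 1L && d[ax] > 1L) {
        dab <- apply_keepdim_sum(dab, ax)
      }
    }
    list(dx_, array(dab, da))
  }
  tp_add_node(tp, y, parents = c(x_id, a_id), vjp = vjp,
              cache = list(x = x, a = a, ab = ab))
}

apply_keepdim_sum <- function(a, axis) {
  d <- dim(a)
  s <- colSums(aperm(a, c(axis, setdiff(1:3, axis))))
  nd <- d; nd[axis] <- 1L
  array(aperm(array(s, c(d[setdiff(1:3, axis)], 1)),
              order(c(setdiff(1:3, axis), axis))), nd)
}

# per-channel instance normalization with learnable gain/bias: standardizes
# each channel map over its spatial extent (the batch-free analogue of batch
# norm; keeps the deep fused branches trainable)
nd_instnorm <- function(tp, x_id, g_id, b_id, eps = 1e-5) {
  x <- nd_value(tp, x_id)
  gam <- nd_value(tp, g_id)
  bet <- nd_value(tp, b_id)
  d <- dim(x)
  n <- d[1] * d[2]
  xm <- matrix(x, n, d[3])
  mu <- colMeans(xm)
  va <- colMeans(xm^2) - mu^2
  s <- sqrt(va + eps)
  xhat <- sweep(sweep(xm, 2, mu), 2, s, "/")
  y <- array(sweep(sweep(xhat, 2, gam, "*"), 2, bet, "+"), d)
  vjp <- function(grad, node) {
    cc <- node$cache
    gm <- matrix(grad, cc$n, length(cc$s))
    dg <- colSums(gm * cc$xhat)
    db <- colSums(gm)
    gh <- sweep(gm, 2, cc$gam, "*")   # dL/dxhat
    dx <- sweep(gh, 2, colMeans(gh)) -
      sweep(cc$xhat, 2, colMeans(gh * cc$xhat), "*")
    dx <- sweep(dx, 2, cc$s, "/")
    list(array(dx, cc$d), dg, db)
  }
  tp_add_node(tp, y, parents = c(x_id, g_id, b_id), vjp = vjp,
              cache = list(xhat = xhat, s = s, gam = gam, d = d, n = n))
}

nd_scale <- function(tp, x_id, k) {
  x <- nd_value(tp, x_id)
  vjp <- function(grad, node) list(grad * node$cache$k)
  tp_add_node(tp, x * k, parents = x_id, vjp = vjp, cache = list(k = k))
}

# spatial soft-argmax: heatmap (h, w, N) -> (N, 2) image-pixel coordinates
nd_softargmax <- function(tp, x_id, tau, stride) {
  x <- nd_value(tp, x_id)
  d <- dim(x)
  gu <- (seq_len(d[2]) - 1) * stride
  gv <- (seq_len(d[1]) - 1) * stride
  coords <- matrix(0, d[3], 2)
  p <- x
  for (c in seq_len(d[3])) {
    m <- x[, , c]
    e <- exp(tau * (m - max(m)))
    pc <- e / sum(e)
    p[, , c] <- pc
    coords[c, ] <- c(sum(colSums(pc) * gu), sum(rowSums(pc) * gv))
  }
  vjp <- function(grad, node) {
    p <- node$cache$p; tau <- node$cache$tau
    gu <- node$cache$gu; gv <- node$cache$gv
    d <- dim(p)
    g <- p
    for (c in seq_len(d[3])) {
      pc <- p[, , c]
      wu <- matrix(gu, d[1], d[2], byrow = TRUE)
      wv <- matrix(gv, d[1], d[2])
      xc <- node$value[c, ]
      g[, , c] <- tau * pc * ((wu - xc[1]) * grad[c, 1] +
                                (wv - xc[2]) * grad[c, 2])
    }
    list(g)
  }
  tp_add_node(tp, coords, parents = x_id, vjp = vjp,
              cache = list(p = p, tau = tau, gu = gu, gv = gv))
}

nd_mse <- function(tp, x_id, target) {
  x <- nd_value(tp, x_id)
  diffv <- x - target
  vjp <- function(grad, node) {
    list(grad * 2 * node$cache$diffv / length(node$cache$diffv))
  }
  tp_add_node(tp, mean(diffv^2), parents = x_id, vjp = vjp,
              cache = list(diffv = diffv))
}

# Reverse pass. seeds: named list mapping node id (as character) to an
# upstream gradient of that node's value. Returns list(param_grads).
tape_backward <- function(tp, seeds) {
  n <- length(tp$nodes)
  grads <- vector("list", n)
  for (id_chr in names(seeds)) {
    id <- as.integer(id_chr)
    g <- seeds[[id_chr]]
    v <- tp$nodes[[id]]$value
    if (is.null(dim(g)) && !is.null(dim(v))) g <- array(g, dim(v))
    grads[[id]] <- if (is.null(grads[[id]])) g else grads[[id]] + g
  }
  param_grads <- list()
  for (id in seq(n, 1)) {
    g <- grads[[id]]
    if (is.null(g)) next
    node <- tp$nodes[[id]]
    if (!is.null(node$param)) {
      pg <- param_grads[[node$param]]
      param_grads[[node$param]] <- if (is.null(pg)) g else pg + g
    }
    if (is.null(node$vjp)) next
    pgrads <- node$vjp(g, node)
    for (k in seq_along(node$parents)) {
      pid <- node$parents[k]
      pg <- pgrads[[k]]
      if (is.null(pg)) next
      grads[[pid]] <- if (is.null(grads[[pid]])) pg else grads[[pid]] + pg
    }
    grads[[id]] <- NULL  # free
  }
  param_grads
}
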