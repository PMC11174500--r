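#' PnP problem specification
#'
#' Bundles 2D-3D correspondences for the back-propagatable PnP layer:
#' predicted projections `x`, optional ground-truth projections `x_star`
#' (weighted by `lambda` in the training loss only), the 3D implicit feature
#' points `z`, and camera intrinsics. Points flagged unusable (invisible or
#' `NA`) are dropped symmetrically from every sum; at least 4 non-collinear
#' usable correspondences are required.
#'
#' @param x N x 2 predicted projections (px).
#' @param z N x 3 model-space points, or a `feature_points3d`.
#' @param K A `camera_intrinsics`.
#' @param x_star Optional N x 2 ground-truth projections.
#' @param lambda Non-negative weight of the `x_star` reprojection term.
#' @param visible Optional logical mask of usable correspondences.
#' @return A `pnp_problem` object.
#' @export
pnp_problem <- function(x, z, K, x_star = NULL, lambda = 1, visible = NULL) {
  if (inherits(z, "feature_points3d")) z <- z$points
  if (inherits(x, "projections2d")) {
    if (is.null(visible)) visible <- x$visible
    x <- x$uv
  }
  x <- matrix(as.numeric(x), ncol = 2)
  z <- as_points3(z)
  stopifnot(nrow(x) == nrow(z), lambda >= 0)
  usable <- !is.na(x[, 1]) & !is.na(x[, 2])
  if (!is.null(visible)) usable <- usable & visible
  if (!is.null(x_star)) {
    x_star <- matrix(as.numeric(x_star), ncol = 2)
    stopifnot(nrow(x_star) == nrow(x))
  }
  if (sum(usable) < 4) stop("need at least 4 usable correspondences")
  zu <- z[usable, , drop = FALSE]
  sv <- svd(sweep(zu, 2, colMeans(zu)))$d
  if (sv[2] < 1e-12 * max(sv[1], 1)) {
    stop("usable 3D points are collinear")
  }
  structure(list(x = x, x_star = x_star, z = z, K = K,
                 lambda = lambda, usable = usable),
            class = "pnp_problem")
}

#' Reprojection loss
#'
#' `l_p = sum_i ||x_i - pi(y, z_i, K)||^2 + lambda * sum_i ||x*_i - pi(y,
#' z_i, K)||^2`, summed over usable correspondences (the same mask applied
#' to both sums). Zero iff every used `x_i` (and `x*_i` when `lambda > 0`)
#' coincides with its projection.
#'
#' @inheritParams pnp_problem
#' @param pose A `pose6d` (the `y` argument of the loss).
#' @return Scalar loss (px^2).
#' @export
reprojection_loss <- function(x, x_star = NULL, pose, z, K, lambda = 1,
                              visible = NULL) {
  pb <- pnp_problem(x, z, K, x_star = x_star, lambda = lambda,
                    visible = visible)
  u <- pb$usable
  proj <- project_points(pb$z[u, , drop = FALSE], pose, K)
  loss <- sum((pb$x[u, ] - proj$uv)^2)
  if (!is.null(pb$x_star) && lambda > 0) {
    loss <- loss + lambda * sum((pb$x_star[u, ] - proj$uv)^2)
  }
  loss
}

# loss + analytic gradients w.r.t. x (N x 2) and pose 6-vector. The pose
# gradient with x_star = NULL, lambda = 0 is the stationarity function f of
# the PnP solve.
reprojection_loss_grads <- function(problem, pose) {
  u <- problem$usable
  zu <- problem$z[u, , drop = FALSE]
  pj <- projection_jacobian(zu, pose, problem$K)
  r <- problem$x[u, , drop = FALSE] - pj$uv   # N_u x 2
  loss <- sum(r^2)
  Jm <- matrix(pj$J, 2 * nrow(zu), 6)
  dpose <- -2 * as.numeric(crossprod(Jm, as.numeric(r)))
  dx <- matrix(0, nrow(problem$x), 2)
  dx[u, ] <- 2 * r
  if (!is.null(problem$x_star) && problem$lambda > 0) {
    rs <- problem$x_star[u, , drop = FALSE] - pj$uv
    loss <- loss + problem$lambda * sum(rs^2)
    dpose <- dpose -
      2 * problem$lambda * as.numeric(crossprod(Jm, as.numeric(rs)))
  }
  list(loss = loss, dx = dx, dpose = dpose)
}

# stationarity function f(x, y, z, K) = d(sum ||x - pi(y)||^2)/dy at pose
# 6-vector v6 (x-term only; the lambda term never enters the solve)
pnp_stationarity <- function(problem, v6) {
  pose <- pose_from_vec6(v6)
  u <- problem$usable
  zu <- problem$z[u, , drop = FALSE]
  pj <- projection_jacobian(zu, pose, problem$K)
  r <- problem$x[u, , drop = FALSE] - pj$uv
  -2 * as.numeric(crossprod(matrix(pj$J, 2 * nrow(zu), 6), as.numeric(r)))
}

#' Solve the PnP problem
#'
#' Forward pass of the BPnP layer: finds the pose minimizing the
#' reprojection error of the predicted points (the `x` term only; the
#' ground-truth term contributes to the training loss, not to the solve).
#' Levenberg-Marquardt on the 6-dof (axis-angle, translation)
#' parameterization, initialized by a closed-form DLT estimate (or the
#' caller's `init`), with 8 deterministic rotation restarts when the best
#' residual exceeds `restart_tol`. Convergence is certified by the
#' stationarity condition `||d l_p / d y||_inf < grad_tol`.
#'
#' @param problem A [pnp_problem()].
#' @param init Optional `pose6d` initialization (e.g. warm start).
#' @param grad_tol Stationarity tolerance (default 1e-8).
#' @param max_iter Maximum LM iterations per start (default 200).
#' @param damping Initial LM damping (default 1e-3).
#' @param restart_tol Residual (px^2) above which rotation restarts are
#'   tried; default `4 * n_usable` (rms 2 px).
#' @return A `pnp_solution`: list with `pose`, `residual` (final loss),
#'   `converged`, `iterations`. Never throws on non-convergence; returns the
#'   best-effort pose with `converged = FALSE`.
#' @export
solve_pnp <- function(problem, init = NULL, grad_tol = 1e-8,
                      max_iter = 200L, damping = 1e-3, restart_tol = NULL) {
  stopifnot(inherits(problem, "pnp_problem"))
  n_use <- sum(problem$usable)
  zu <- problem$z[problem$usable, , drop = FALSE]
  sv <- svd(sweep(zu, 2, colMeans(zu)))$d
  coplanar <- sv[3] < 1e-9 * max(sv[1], 1)
  # coplanar configurations carry the classic two-fold pose ambiguity:
  # always probe the rotation restarts there
  if (is.null(restart_tol)) {
    restart_tol <- if (coplanar) 1e-8 * n_use else 4 * n_use
  }
  starts <- list()
  if (!is.null(init)) starts <- c(starts, list(init))
  if (coplanar) {
    starts <- c(starts, tryCatch(pnp_planar_init(problem),
                                 error = function(e) list()))
  } else {
    dlt <- tryCatch(pnp_dlt_init(problem), error = function(e) NULL)
    if (!is.null(dlt)) starts <- c(starts, list(dlt))
  }
  if (length(starts) == 0) starts <- list(pose6d(diag(3), c(0, 0, 1)))

  best <- NULL
  all_sols <- list()
  total_iter <- 0L
  run <- function(start) {
    lm_pnp(problem, start, grad_tol = grad_tol, max_iter = max_iter,
           damping = damping)
  }
  for (s in starts) {
    sol <- run(s)
    total_iter <- total_iter + sol$iterations
    all_sols[[length(all_sols) + 1]] <- sol
    if (is.null(best) || sol$residual < best$residual) best <- sol
    if (best$converged && best$residual <= restart_tol) break
  }
  if (is.finite(restart_tol) &&
      !(best$converged && best$residual <= restart_tol)) {
    base <- best$pose
    for (aa in restart_rotations()) {
      s <- pose6d(rotmat_from_axis_angle(aa) %*% base$R, base$t)
      s <- refit_translation(problem, s)
      sol <- run(s)
      total_iter <- total_iter + sol$iterations
      all_sols[[length(all_sols) + 1]] <- sol
      if (sol$residual < best$residual) best <- sol
    }
  }
  best$iterations <- total_iter
  # distinct stationary points found along the way, sorted by residual:
  # near-planar keypoint configurations have a two-fold ambiguity whose
  # second sheet callers may need to disambiguate (e.g. by contour
  # consistency)
  ord <- order(vapply(all_sols, function(s) s$residual, 0.0))
  cands <- list()
  for (k in ord) {
    s <- all_sols[[k]]
    if (!is.finite(s$residual)) next
    dup <- any(vapply(cands, function(c2) {
      rotation_geodesic_deg(c2$pose, s$pose) < 5 &&
        sqrt(sum((c2$pose$t - s$pose$t)^2)) < 0.05 * max(1, sqrt(sum(s$pose$t^2)))
    }, TRUE))
    if (!dup) cands[[length(cands) + 1]] <- s
    if (length(cands) >= 4) break
  }
  best$candidates <- cands
  best
}

restart_rotations <- function() {
  d <- 1 / sqrt(3)
  list(c(pi / 2, 0, 0), c(0, pi / 2, 0), c(0, 0, pi / 2),
       c(pi, 0, 0), c(0, pi, 0), c(0, 0, pi),
       2 * pi / 3 * c(d, d, d), -2 * pi / 3 * c(d, d, d))
}

# given a rotation, least-squares translation from the linearized projection
# equations u' (r3 z + t3) = r1 z + t1, v' (r3 z + t3) = r2 z + t2
refit_translation <- function(problem, pose) {
  u <- problem$usable
  zu <- problem$z[u, , drop = FALSE]
  xu <- problem$x[u, , drop = FALSE]
  K <- problem$K
  up <- (xu[, 1] - K$cx) / K$fx
  vp <- (xu[, 2] - K$cy) / K$fy
  rz <- zu %*% t(pose$R)  # rows: R z
  n <- nrow(zu)
  A <- matrix(0, 2 * n, 3)
  b <- numeric(2 * n)
  A[seq(1, 2 * n, 2), ] <- cbind(rep(1, n), 0, -up)
  A[seq(2, 2 * n, 2), ] <- cbind(0, rep(1, n), -vp)
  b[seq(1, 2 * n, 2)] <- up * rz[, 3] - rz[, 1]
  b[seq(2, 2 * n, 2)] <- vp * rz[, 3] - rz[, 2]
  t_ls <- tryCatch(qr.solve(A, b), error = function(e) pose$t)
  if (t_ls[3] <= 0) t_ls <- pose$t
  pose6d(pose$R, t_ls)
}

lm_pnp <- function(problem, init, grad_tol, max_iter, damping) {
  v <- pose_to_vec6(init)
  u <- problem$usable
  zu <- problem$z[u, , drop = FALSE]
  xu <- problem$x[u, , drop = FALSE]
  nu <- nrow(zu)
  mu <- damping
  eval_rj <- function(v) {
    pj <- projection_jacobian(zu, pose_from_vec6(v), problem$K)
    if (anyNA(pj$uv)) return(NULL)  # point behind camera: invalid region
    # flatten consistently with the (n, 2, 6) array layout: point-major,
    # then coordinate
    r <- as.numeric(pj$uv - xu)                 # 2N
    J <- matrix(pj$J, 2 * nu, 6)
    list(r = r, J = J)
  }
  rj <- eval_rj(v)
  if (is.null(rj)) {
    return(structure(list(pose = init, residual = Inf, converged = FALSE,
                          iterations = 0L), class = "pnp_solution"))
  }
  loss <- sum(rj$r^2)
  converged <- FALSE
  it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    g <- 2 * as.numeric(crossprod(rj$J, rj$r))
    gnorm <- max(abs(g))
    if (gnorm < grad_tol) { converged <- TRUE; break }
    H <- 2 * crossprod(rj$J)
    step_ok <- FALSE
    for (tries in 1:30) {
      delta <- tryCatch(
        solve(H + mu * diag(pmax(diag(H), 1e-12)), -g),
        error = function(e) NULL
      )
      if (!is.null(delta)) {
        v_new <- v + delta
        rj_new <- eval_rj(v_new)
        if (!is.null(rj_new)) {
          loss_new <- sum(rj_new$r^2)
          g_new <- 2 * as.numeric(crossprod(rj_new$J, rj_new$r))
          # accept on loss decrease, or - near the optimum, where loss
          # differences fall below double precision - on gradient decrease
          if (loss_new < loss ||
              (loss_new < loss * (1 + 1e-12) && max(abs(g_new)) < gnorm)) {
            v <- v_new; rj <- rj_new; loss <- loss_new
            mu <- max(mu / 3, 1e-14)
            step_ok <- TRUE
            break
          }
        }
      }
      mu <- mu * 4
    }
    if (!step_ok) break
  }
  if (!converged) {
    g <- 2 * as.numeric(crossprod(rj$J, rj$r))
    converged <- max(abs(g)) < grad_tol
  }
  structure(list(pose = pose_from_vec6(v), residual = loss,
                 converged = converged, iterations = it),
            class = "pnp_solution")
}

#' @export
print.pnp_solution <- function(x, ...) {
  cat(sprintf("pnp_solution: residual %.4g px^2, %s in %d iterations\n",
              x$residual, if (x$converged) "converged" else "NOT converged",
              x$iterations))
  invisible(x)
}

# closed-form DLT initialization: homogeneous linear solve for [R|t] on
# normalized image coordinates, SVD orthogonalization, cheirality sign fix
pnp_dlt_init <- function(problem) {
  u <- problem$usable
  zu <- problem$z[u, , drop = FALSE]
  xu <- problem$x[u, , drop = FALSE]
  K <- problem$K
  n <- nrow(zu)
  if (n < 6) stop("DLT needs >= 6 points")
  up <- (xu[, 1] - K$cx) / K$fx
  vp <- (xu[, 2] - K$cy) / K$fy
  A <- matrix(0, 2 * n, 12)
  for (k in seq_len(n)) {
    Z1 <- c(zu[k, ], 1)
    A[2 * k - 1, ] <- c(Z1, rep(0, 4), -up[k] * Z1)
    A[2 * k, ] <- c(rep(0, 4), Z1, -vp[k] * Z1)
  }
  p <- svd(A, nu = 0)$v[, 12]
  P <- matrix(p, 3, 4, byrow = TRUE)
  M <- P[, 1:3]
  sv <- svd(M)
  s <- mean(sv$d)
  if (s < 1e-12) stop("degenerate DLT solution")
  Rm <- sv$u %*% diag(c(1, 1, det(sv$u %*% t(sv$v)))) %*% t(sv$v)
  t_ <- P[, 4] / s
  depths <- zu %*% Rm[3, ] + t_[3]
  if (mean(depths > 0) < 0.5) {
    Rm <- sv$u %*% diag(c(-1, -1, det(sv$u %*% t(sv$v)))) %*% t(sv$v)
    # recompute with flipped sign of P
    t_ <- -P[, 4] / s
  }
  pose <- pose6d(Rm, t_)
  refit_translation(problem, pose)
}

# homography-based initialization for coplanar 3D points: fits the plane,
# estimates the plane-to-normalized-image homography by 2D DLT, and
# decomposes it into [r1 r2 | t]
pnp_planar_init <- function(problem) {
  u <- problem$usable
  zu <- problem$z[u, , drop = FALSE]
  xu <- problem$x[u, , drop = FALSE]
  K <- problem$K
  n <- nrow(zu)
  ctr <- colMeans(zu)
  sv <- svd(sweep(zu, 2, ctr))
  e1 <- sv$v[, 1]; e2 <- sv$v[, 2]
  s2 <- sweep(zu, 2, ctr) %*% cbind(e1, e2)   # plane coordinates
  up <- (xu[, 1] - K$cx) / K$fx
  vp <- (xu[, 2] - K$cy) / K$fy
  A <- matrix(0, 2 * n, 9)
  for (k in seq_len(n)) {
    S1 <- c(s2[k, ], 1)
    A[2 * k - 1, ] <- c(S1, rep(0, 3), -up[k] * S1)
    A[2 * k, ] <- c(rep(0, 3), S1, -vp[k] * S1)
  }
  Hh <- matrix(svd(A, nu = 0)$v[, 9], 3, 3, byrow = TRUE)
  if (Hh[3, 3] < 0) Hh <- -Hh
  a1 <- Hh[, 1]; a2 <- Hh[, 2]; a3 <- Hh[, 3]
  lam <- 2 / (sqrt(sum(a1^2)) + sqrt(sum(a2^2)))
  r1 <- lam * a1; r2 <- lam * a2
  out <- list()
  for (sgn in c(1, -1)) {
    r3 <- sgn * crossv(r1, r2)
    Rm <- cbind(r1, sgn * r2, r3)
    svR <- svd(Rm)
    Rm <- svR$u %*% diag(c(1, 1, det(svR$u %*% t(svR$v)))) %*% t(svR$v)
    Rw <- Rm %*% t(cbind(e1, e2, crossv(e1, e2)))
    tw <- lam * a3 - as.numeric(Rw %*% ctr)
    if (tw[3] <= 0) next
    pose <- tryCatch(refit_translation(problem, pose6d(Rw, tw)),
                     error = function(e) NULL)
    if (!is.null(pose)) out[[length(out) + 1]] <- pose
  }
  out
}

#' Implicit-function-theorem backward pass
#'
#' Gradient of the PnP pose w.r.t. the 2D input points, via
#' `dy/dx = -[df/dy]^{-1} [df/dx]` where `f = d l_p / d y` is the
#' stationarity function of the solve. `df/dx` is analytic (from the
#' projection Jacobians); `df/dy` (the 6x6 Hessian of the reprojection loss)
#' is obtained by central differences of the analytic gradient (accurate to
#' ~1e-8 relative) and regularized by `+1e-10 I` before inversion.
#'
#' @param solution A converged `pnp_solution`.
#' @param problem The corresponding [pnp_problem()].
#' @param grad_wrt_pose Length-6 upstream gradient w.r.t. the pose 6-vector
#'   (axis-angle, translation) at the solution.
#' @param cond_max Maximum acceptable Hessian condition number.
#' @return N x 2 gradient w.r.t. `x` (zero rows for unused points).
#' @export
implicit_backward <- function(solution, problem, grad_wrt_pose,
                              cond_max = 1e12) {
  stopifnot(inherits(solution, "pnp_solution"), length(grad_wrt_pose) == 6)
  if (!solution$converged) stop("implicit backward requires a converged solve")
  v <- pose_to_vec6(solution$pose)
  H <- hessian_fd(function(vv) pnp_stationarity(problem, vv), v)
  H <- (H + t(H)) / 2 + 1e-10 * diag(6)
  cond <- kappa(H, exact = TRUE)
  if (!is.finite(cond) || cond > cond_max) {
    stop(sprintf("PnP Hessian ill-conditioned (condition number %.3g)", cond))
  }
  w <- solve(H, as.numeric(grad_wrt_pose))
  # df_j/dx_{i,c} = -2 J_i[c, j]  =>  grad_x[i, c] = 2 * J_i[c, ] %*% w
  u <- problem$usable
  zu <- problem$z[u, , drop = FALSE]
  pj <- projection_jacobian(zu, solution$pose, problem$K)
  grad_x <- matrix(0, nrow(problem$x), 2)
  idx <- which(u)
  for (k in seq_along(idx)) {
    grad_x[idx[k], ] <- 2 * as.numeric(pj$J[k, , ] %*% w)
  }
  grad_x
}

# central-difference Jacobian of a vector function (used on the analytic
# stationarity gradient, so the result is the loss Hessian)
hessian_fd <- function(fn, v, h_rel = 1e-6) {
  p <- length(v)
  H <- matrix(0, p, p)
  for (j in seq_len(p)) {
    h <- h_rel * max(1, abs(v[j]))
    vp <- v; vp[j] <- vp[j] + h
    vm <- v; vm[j] <- vm[j] - h
    H[, j] <- (fn(vp) - fn(vm)) / (2 * h)
  }
  H
}

#' Back-propagatable PnP layer
#'
#' Composes the forward solve and the implicit backward pass: the returned
#' object carries the pose and a `backward(grad_wrt_pose)` closure mapping
#' an upstream pose gradient (w.r.t. the axis-angle + translation 6-vector)
#' to the gradient w.r.t. the 2D input points, so the reprojection loss can
#' be back-propagated into the keypoint network.
#'
#' @inheritParams pnp_problem
#' @param init Optional warm-start pose.
#' @param ... Passed to [solve_pnp()].
#' @return A `bpnp_layer` object: list with `pose`, `solution`, `problem`
#'   and `backward`. If the solve did not converge, `backward` is `NULL` and
#'   `pose` is best-effort (flagged by `solution$converged`).
#' @export
bpnp_layer <- function(x, z, K, visible = NULL, init = NULL, ...) {
  problem <- pnp_problem(x, z, K, visible = visible)
  solution <- solve_pnp(problem, init = init, ...)
  backward <- NULL
  if (solution$converged) {
    backward <- function(grad_wrt_pose) {
      implicit_backward(solution, problem, grad_wrt_pose)
    }
  }
  structure(list(pose = solution$pose, solution = solution,
                 problem = problem, backward = backward),
            class = "bpnp_layer")
}
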