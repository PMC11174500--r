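test_that("reprojection loss follows its closed forms", {
  inst <- random_pnp_instance(1, noise_sd = 0)
  # exact projections: zero loss
  expect_equal(reprojection_loss(inst$x_clean, NULL, inst$pose, inst$z,
                                 inst$K, lambda = 0), 0, tolerance = 1e-16)
  # 1 px offset on each of 8 points: loss 8
  x_off <- sweep(inst$x_clean, 2, c(1, 0), "+")
  expect_equal(reprojection_loss(x_off, NULL, inst$pose, inst$z, inst$K,
                                 lambda = 0), 8, tolerance = 1e-12)
  # lambda = 1 with x* = x doubles the loss
  l0 <- reprojection_loss(x_off, NULL, inst$pose, inst$z, inst$K, lambda = 0)
  l1 <- reprojection_loss(x_off, x_off, inst$pose, inst$z, inst$K, lambda = 1)
  expect_equal(l1, 2 * l0, tolerance = 1e-12)
  # fewer than 4 usable points is an error
  expect_error(pnp_problem(inst$x[1:3, ], inst$z[1:3, ], inst$K), "at least 4")
})

test_that("noiseless PnP recovers the generating pose exactly", {
  for (s in 1:25) {
    inst <- random_pnp_instance(s, noise_sd = 0)
    sol <- solve_pnp(pnp_problem(inst$x_clean, inst$z, inst$K))
    expect_true(sol$converged)
    expect_lt(rotation_geodesic_deg(sol$pose, inst$pose), 1e-4)
    expect_lt(sqrt(sum((sol$pose$t - inst$pose$t)^2)), 1e-6)
  }
})

test_that("converged solves certify stationarity and degrade smoothly with noise", {
  res_by_sigma <- sapply(c(0.1, 0.5, 1), function(sig) {
    r <- sapply(1:20, function(s) {
      inst <- random_pnp_instance(100 + s, noise_sd = sig)
      pb <- pnp_problem(inst$x, inst$z, inst$K)
      sol <- solve_pnp(pb)
      expect_true(sol$converged)
      f <- maskpose:::pnp_stationarity(pb, maskpose:::pose_to_vec6(sol$pose))
      expect_lt(max(abs(f)), 1e-6)
      c(sol$residual, rotation_geodesic_deg(sol$pose, inst$pose))
    })
    rowMeans(r)
  })
  # residual scales like n * 2 sigma^2 and pose error grows with sigma
  expect_true(all(diff(res_by_sigma[1, ]) > 0))
  expect_true(all(diff(res_by_sigma[2, ]) > 0))
  expect_lt(abs(res_by_sigma[1, 2] / (8 * 2 * 0.25) - 1), 0.6)
})

test_that("implicit backward matches the re-solve finite-difference oracle", {
  set.seed(77)
  for (s in c(3, 14, 25)) {
    inst <- random_pnp_instance(s, noise_sd = 0.5)
    pb <- pnp_problem(inst$x, inst$z, inst$K)
    sol <- solve_pnp(pb)
    gy <- rnorm(6)
    gx <- implicit_backward(sol, pb, gy)
    gx_fd <- bpnp_fd_oracle(inst$x, inst$z, inst$K, sol, gy)
    expect_lt(norm(gx - gx_fd, "F") / norm(gx_fd, "F"), 1e-3)
  }
  # zero upstream gradient: zero output
  inst <- random_pnp_instance(4)
  pb <- pnp_problem(inst$x, inst$z, inst$K)
  sol <- solve_pnp(pb)
  expect_equal(implicit_backward(sol, pb, rep(0, 6)), matrix(0, 8, 2))
})

test_that("gradient mass splits equally across duplicated points", {
  inst <- random_pnp_instance(8, noise_sd = 0.3)
  # duplicate point 1 (same 3D point and same observation listed twice)
  z2 <- rbind(inst$z, inst$z[1, ])
  x2 <- rbind(inst$x, inst$x[1, ])
  pb <- pnp_problem(x2, z2, inst$K)
  sol <- solve_pnp(pb)
  set.seed(1); gy <- rnorm(6)
  gx <- implicit_backward(sol, pb, gy)
  expect_equal(gx[1, ], gx[9, ], tolerance = 1e-9)
  gx_fd <- bpnp_fd_oracle(x2, z2, inst$K, sol, gy)
  expect_lt(norm(gx - gx_fd, "F") / norm(gx_fd, "F"), 1e-3)
})

test_that("recovered rotation is equivariant to a world-frame rotation", {
  inst <- random_pnp_instance(5, noise_sd = 0)
  sol <- solve_pnp(pnp_problem(inst$x_clean, inst$z, inst$K))
  Q <- rotmat_from_axis_angle(c(0.4, -0.2, 0.9))
  zq <- inst$z %*% Q   # rotate model frame by Q' (points p -> Q' p)
  solq <- solve_pnp(pnp_problem(inst$x_clean, zq, inst$K))
  expect_lt(max(abs(solq$pose$R - sol$pose$R %*% Q)), 1e-6)
  expect_lt(max(abs(solq$pose$t - sol$pose$t)), 1e-6)
})

test_that("the BPnP layer composes with the reprojection loss end to end", {
  inst <- random_pnp_instance(9, noise_sd = 0.4)
  x <- inst$x
  layer <- bpnp_layer(x, inst$z, inst$K)
  expect_true(layer$solution$converged)
  # composed loss: l(x) = reprojection_loss(x, x*, y(x)) with x* fixed
  x_star <- inst$x_clean
  composed <- function(xm) {
    lay <- bpnp_layer(xm, inst$z, inst$K, init = layer$pose)
    reprojection_loss(xm, x_star, lay$pose, inst$z, inst$K, lambda = 1)
  }
  pb <- pnp_problem(x, inst$z, inst$K, x_star = x_star, lambda = 1)
  lg <- maskpose:::reprojection_loss_grads(pb, layer$pose)
  g_total <- lg$dx + layer$backward(lg$dpose)
  h <- 1e-4
  g_fd <- matrix(0, 8, 2)
  for (i in 1:8) for (cc in 1:2) {
    xp <- x; xp[i, cc] <- xp[i, cc] + h
    xm <- x; xm[i, cc] <- xm[i, cc] - h
    g_fd[i, cc] <- (composed(xp) - composed(xm)) / (2 * h)
  }
  expect_lt(norm(g_total - g_fd, "F") / norm(g_fd, "F"), 1e-3)

  # a small step along the negative gradient decreases the composed loss
  l0 <- composed(x)
  for (s in 1:5) {
    set.seed(200 + s)
    inst2 <- random_pnp_instance(300 + s, noise_sd = 1)
    lay2 <- bpnp_layer(inst2$x, inst2$z, inst2$K)
    pb2 <- pnp_problem(inst2$x, inst2$z, inst2$K, x_star = inst2$x_clean,
                       lambda = 1)
    lg2 <- maskpose:::reprojection_loss_grads(pb2, lay2$pose)
    g2 <- lg2$dx + lay2$backward(lg2$dpose)
    l_before <- reprojection_loss(inst2$x, inst2$x_clean, lay2$pose, inst2$z,
                                  inst2$K, lambda = 1)
    x_new <- inst2$x - 1e-4 * g2
    lay3 <- bpnp_layer(x_new, inst2$z, inst2$K, init = lay2$pose)
    l_after <- reprojection_loss(x_new, inst2$x_clean, lay3$pose, inst2$z,
                                 inst2$K, lambda = 1)
    expect_lt(l_after, l_before)
  }
  # stationarity: x already optimal for its own solve gives zero x-term
  sol0 <- solve_pnp(pnp_problem(inst$x_clean, inst$z, inst$K))
  f0 <- maskpose:::pnp_stationarity(pnp_problem(inst$x_clean, inst$z, inst$K),
                                    maskpose:::pose_to_vec6(sol0$pose))
  expect_lt(max(abs(f0)), 1e-8)
})

test_that("coplanar keypoint sets are still solved via the planar path", {
  mesh <- toy_instrument("tube")
  kp <- farthest_point_sampling(mesh, 8L)
  K <- test_K640()
  for (s in 1:5) {
    p <- sample_poses(default_pose_ranges(mesh), 1, seed = 400 + s)[[1]]
    proj <- project_points(kp, p, K)
    sol <- solve_pnp(pnp_problem(proj$uv, kp, K))
    expect_lt(rotation_geodesic_deg(sol$pose, p), 1e-4)
  }
})
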