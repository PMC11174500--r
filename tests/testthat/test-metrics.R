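random_pose_pair <- function(seed) {
  set.seed(seed)
  list(pred = pose6d(rotation = rnorm(3), translation = rnorm(3) + c(0, 0, 6)),
       gt = pose6d(rotation = rnorm(3), translation = rnorm(3) + c(0, 0, 6)))
}

test_that("ADD matches its closed forms and the per-point loop oracle", {
  pts <- matrix(rnorm(150), 50, 3)
  p <- random_pose_pair(1)
  expect_equal(add_metric(pts, p$gt, p$gt), 0)
  shifted <- pose6d(p$gt$R, p$gt$t + c(0.3, 0, 0))
  expect_equal(add_metric(pts, shifted, p$gt), 0.3, tolerance = 1e-12)
  # naive loop oracle
  oracle <- mean(vapply(seq_len(nrow(pts)), function(i) {
    a <- p$pred$R %*% pts[i, ] + p$pred$t
    b <- p$gt$R %*% pts[i, ] + p$gt$t
    sqrt(sum((a - b)^2))
  }, 0.0))
  expect_equal(add_metric(pts, p$pred, p$gt), oracle, tolerance = 1e-12)
  expect_error(add_metric(matrix(0, 0, 3), p$pred, p$gt), "empty")
})

test_that("ADD-S vanishes under an exact symmetry while ADD does not", {
  # centered square, prediction rotated 90 degrees about its symmetry axis
  sq <- rbind(c(1, 0, 0), c(0, 1, 0), c(-1, 0, 0), c(0, -1, 0))
  gt <- pose6d(translation = c(0, 0, 5))
  pred <- pose6d(rotation = c(0, 0, pi / 2), translation = c(0, 0, 5))
  # exhaustive nearest-point oracle on the 4-point set
  a <- pose_apply(pred, sq); b <- pose_apply(gt, sq)
  oracle <- mean(apply(a, 1, function(p) {
    min(sqrt(colSums((t(b) - p)^2)))
  }))
  expect_equal(oracle, 0)
  expect_equal(add_s_metric(sq, pred, gt), 0)
  expect_gt(add_metric(sq, pred, gt), 1)
})

test_that("ADD-S <= ADD and the compiled scan equals the O(n^2) oracle", {
  for (s in 1:20) {
    set.seed(s)
    n <- sample(20:300, 1)
    pts <- matrix(rnorm(3 * n), n, 3)
    p <- random_pose_pair(1000 + s)
    adds <- add_s_metric(pts, p$pred, p$gt)
    add <- add_metric(pts, p$pred, p$gt)
    expect_lte(adds, add + 1e-12)
    a <- pose_apply(p$pred, pts); b <- pose_apply(p$gt, pts)
    oracle <- mean(vapply(seq_len(n), function(i) {
      min(sqrt(rowSums(sweep(b, 2, a[i, ])^2)))
    }, 0.0))
    expect_equal(adds, oracle, tolerance = 1e-12)
  }
})

test_that("2D projection error matches similar triangles and the loop oracle", {
  K <- test_K640()
  pts <- matrix(rnorm(24) * 0.3, 8, 3)
  gt <- pose6d(translation = c(0, 0, 5))
  expect_equal(projection_error_2d(pts, gt, gt, K), 0)
  # lateral shift of fx * dx / Z = 525 * dx / 5 = 5 px for dx = 5/105
  pred <- pose6d(gt$R, gt$t + c(5 * 5 / K$fx, 0, 0))
  pts_flat <- cbind(pts[, 1:2], 0)  # all points at depth exactly 5
  expect_equal(projection_error_2d(pts_flat, pred, gt, K), 5, tolerance = 1e-9)
  # random instance vs naive loop
  p <- random_pose_pair(77)
  pu <- project_points(pts, p$pred, K)$uv
  gu <- project_points(pts, p$gt, K)$uv
  oracle <- mean(sqrt(rowSums((pu - gu)^2)))
  expect_equal(projection_error_2d(pts, p$pred, p$gt, K), oracle,
               tolerance = 1e-12)
  # behind-camera flagging
  behind <- pose6d(translation = c(0, 0, -5))
  expect_warning(v <- projection_error_2d(pts, behind, gt, K), "behind")
  expect_true(is.na(v))
})

test_that("IOU matches closed-form cases", {
  a <- matrix(0L, 10, 10); a[1:4, 1:4] <- 1L
  expect_equal(iou(a, a), 1)
  b <- matrix(0L, 10, 10); b[6:9, 6:9] <- 1L
  expect_equal(iou(a, b), 0)
  # half-overlapping equal rectangles: (a/2) / (3a/2) = 1/3
  c1 <- matrix(0L, 10, 10); c1[1:4, 1:4] <- 1L
  c2 <- matrix(0L, 10, 10); c2[1:4, 3:6] <- 1L
  expect_equal(iou(c1, c2), 1 / 3)
  expect_warning(z <- iou(matrix(0L, 5, 5), matrix(0L, 5, 5)), "empty")
  expect_equal(z, 0)
  expect_error(iou(matrix(0L, 5, 5), matrix(0L, 4, 4)), "shapes")
})

test_that("all four metrics are invariant to a common world-frame change", {
  mesh <- cube_fixture(1)
  pts <- mesh$vertices
  K <- test_K640()
  p <- random_pose_pair(5)
  Q <- pose6d(rotation = c(0.2, 0.5, -0.3), translation = c(0.4, -0.2, 0.1))
  predq <- pose_compose(p$pred, Q)
  gtq <- pose_compose(p$gt, Q)
  ptsq <- pose_apply(pose_inverse(Q), pts)
  expect_equal(add_metric(ptsq, predq, gtq), add_metric(pts, p$pred, p$gt),
               tolerance = 1e-9)
  expect_equal(add_s_metric(ptsq, predq, gtq),
               add_s_metric(pts, p$pred, p$gt), tolerance = 1e-9)
  expect_equal(projection_error_2d(ptsq, predq, gtq, K),
               projection_error_2d(pts, p$pred, p$gt, K), tolerance = 1e-9)
})

test_that("evaluate_poses aggregates threshold accuracies correctly", {
  mesh <- cube_fixture(1)
  K <- test_K()
  gt <- replicate(4, cube_pose(), simplify = FALSE)
  # all perfect: 100% everywhere, IOU 1
  masks <- lapply(gt, function(p) rasterize_hard(mesh, p, K))
  rep1 <- evaluate_poses(gt, gt, mesh, K, masks = masks)
  expect_equal(rep1$summary$acc_add, 100)
  expect_equal(unname(rep1$summary$acc_px), c(100, 100))
  expect_equal(rep1$summary$mean_iou, 1)
  # exactly 3 of 4 under the ADD threshold: 75%
  d <- mesh_diameter(mesh)
  pred <- list(gt[[1]], gt[[2]], gt[[3]],
               pose6d(gt[[4]]$R, gt[[4]]$t + c(0.2 * d, 0, 0)))
  rep2 <- evaluate_poses(pred, gt, mesh, K)
  expect_equal(rep2$summary$acc_add, 75)
  # 5 px accuracy >= 3 px accuracy (set inclusion)
  expect_gte(rep2$summary$acc_px[1], rep2$summary$acc_px[2])
  # missing ground truth: IOU-only mode
  rep3 <- evaluate_poses(gt, NULL, mesh, K, masks = masks)
  expect_equal(rep3$summary$mode, "iou_only")
  expect_equal(rep3$summary$mean_iou, 1)
  # report files
  jp <- file.path(tempdir(), "rep.json"); cp <- file.path(tempdir(), "rep.csv")
  write_eval_report(rep2, jp, cp)
  expect_true(file.exists(jp) && file.exists(cp))
  expect_equal(nrow(utils::read.csv(cp)), 4)
})
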