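test_that("hard rasterization matches the analytic projected-hull area", {
  # cube at depth 4; silhouette large enough that pixel-center quantization
  # stays under the 2% band (error scales as ~perimeter/area)
  K <- camera_intrinsics(250, 250, 160, 120, 320, 240)
  pose <- pose6d(rotation = c(0.3, 0.2, 0.1), translation = c(0, 0, 4))
  m <- rasterize_hard(cube_fixture(1), pose, K)
  corners <- as.matrix(expand.grid(c(-.5, .5), c(-.5, .5), c(-.5, .5)))
  uv <- project_points(corners, pose, K)$uv
  hull <- chull(uv)
  hv <- uv[hull, ]
  shoelace <- abs(sum(hv[, 1] * hv[c(2:nrow(hv), 1), 2] -
                        hv[c(2:nrow(hv), 1), 1] * hv[, 2])) / 2
  expect_lt(abs(sum(m) - shoelace) / shoelace, 0.02)
})

test_that("single-triangle rasterization equals per-pixel point-in-triangle", {
  K <- test_K()
  tri <- tri_mesh(rbind(c(-0.02, -0.01, 1), c(0.04, 0, 1), c(0, 0.03, 1)),
                  matrix(1:3, 1))
  m <- rasterize_hard(tri, pose6d(), K)
  uv <- project_points(tri$vertices, pose6d(), K)$uv
  sgn <- function(a, b, p) (b[1] - a[1]) * (p[2] - a[2]) - (b[2] - a[2]) * (p[1] - a[1])
  for (iy in 0:(K$height - 1)) {
    for (ix in 0:(K$width - 1)) {
      p <- c(ix, iy)
      d1 <- sgn(uv[1, ], uv[2, ], p); d2 <- sgn(uv[2, ], uv[3, ], p)
      d3 <- sgn(uv[3, ], uv[1, ], p)
      inside <- (d1 >= 0 && d2 >= 0 && d3 >= 0) || (d1 <= 0 && d2 <= 0 && d3 <= 0)
      expect_equal(m[iy + 1, ix + 1], as.integer(inside))
    }
  }
})

test_that("mesh behind the camera gives an empty mask with a warning", {
  K <- test_K()
  expect_warning(m <- rasterize_hard(cube_fixture(1),
                                     pose6d(translation = c(0, 0, -1)), K),
                 "empty")
  expect_true(all(m == 0L))
})

test_that("soft rasterization approaches the hard mask with sharpness", {
  K <- test_K()
  pose <- cube_pose()
  hard <- rasterize_hard(cube_fixture(1), pose, K)
  # interior pixel ~1, and mean |soft - hard| decreases monotonically
  devs <- sapply(c(1, 2, 4, 8), function(s) {
    soft <- rasterize_soft(cube_fixture(1), pose, K, sharpness = s)
    mean(abs(as.numeric(soft) - as.numeric(hard)))
  })
  expect_true(all(diff(devs) < 0))
  # a pixel deep inside some face sees sigmoid of a large positive distance
  soft1 <- rasterize_soft(cube_fixture(1), pose, K, sharpness = 1)
  expect_gt(max(soft1), 0.99)
})

test_that("a pixel on a projected edge gets value 0.5 from that face", {
  # single triangle whose projected edge passes through pixel centers
  K <- test_K()
  tri <- tri_mesh(rbind(c(-0.2, 0, 1), c(0.2, 0, 1), c(0, -0.2, 1)),
                  matrix(1:3, 1))
  soft <- rasterize_soft(tri, pose6d(), K, sharpness = 1)
  # edge (v1, v2) projects onto v = cy exactly; pick a pixel on it
  expect_equal(soft[61, 81], 0.5, tolerance = 1e-9)
})

test_that("hard mask equals thresholded soft mask away from the contour", {
  K <- test_K()
  pose <- cube_pose()
  hard <- rasterize_hard(cube_fixture(1), pose, K)
  soft <- rasterize_soft(cube_fixture(1), pose, K, sharpness = 50)
  thr <- (matrix(as.numeric(soft), K$height) >= 0.5) + 0L
  disagree <- which(thr != hard, arr.ind = TRUE)
  if (nrow(disagree) > 0) {
    edge <- which(hard == 1L, arr.ind = TRUE)
    for (r in seq_len(nrow(disagree))) {
      d <- min(sqrt((edge[, 1] - disagree[r, 1])^2 +
                      (edge[, 2] - disagree[r, 2])^2))
      expect_lt(d, 1.5)  # within ~1 px of the contour
    }
  }
  succeed()
})

test_that("silhouette area scales as 1/Z^2", {
  # small object relative to depth (far-field), so the front-face
  # perspective bias stays inside the 5% band
  K <- camera_intrinsics(2000, 2000, 320, 240, 640, 480)
  a1 <- sum(rasterize_hard(cube_fixture(0.1), pose6d(translation = c(0, 0, 3)), K))
  a2 <- sum(rasterize_hard(cube_fixture(0.1), pose6d(translation = c(0, 0, 6)), K))
  expect_lt(abs(a1 / a2 - 4), 4 * 0.05)
})

test_that("render loss obeys its closed forms and decreases toward the truth", {
  m0 <- mask_image(matrix(0L, 10, 10), "binary")
  expect_equal(render_loss(m0, m0), 0)
  half <- mask_image(matrix(0.5, 10, 10), "soft")
  expect_equal(render_loss(half, m0), 0.25)
  expect_error(render_loss(matrix(0, 2, 2), matrix(0, 3, 3)), "shapes differ")

  # line scan from a 5-degree-perturbed pose toward the truth
  K <- test_K()
  gt <- cube_pose()
  target <- rasterize_hard(cube_fixture(1), gt, K)
  v_gt <- maskpose:::pose_to_vec6(gt)
  axis <- c(1, 0.3, -0.2); axis <- axis / sqrt(sum(axis^2))
  v_far <- v_gt + c(axis * 5 * pi / 180, 0, 0, 0)
  losses <- sapply(c(1, 0.6, 0.3, 0), function(s) {
    v <- v_gt + s * (v_far - v_gt)
    render_loss(rasterize_soft(cube_fixture(1),
                               maskpose:::pose_from_vec6(v), K, 10), target)
  })
  expect_true(all(diff(losses) < 0))
})

test_that("soft rasterizer pose gradient matches central finite differences", {
  K <- test_K()
  gt <- pose6d(rotation = c(0.25, 0.18, 0.12), translation = c(0.12, 0, 4.1))
  target <- rasterize_hard(cube_fixture(1), gt, K)
  pose <- cube_pose()
  res <- render_loss_pose_grad(cube_fixture(1), pose, K, target, sharpness = 10)
  v0 <- maskpose:::pose_to_vec6(pose)
  fd <- sapply(1:6, function(i) {
    h <- 1e-4
    vp <- v0; vp[i] <- vp[i] + h
    vm <- v0; vm[i] <- vm[i] - h
    lp <- render_loss(rasterize_soft(cube_fixture(1),
                                     maskpose:::pose_from_vec6(vp), K, 10), target)
    lm <- render_loss(rasterize_soft(cube_fixture(1),
                                     maskpose:::pose_from_vec6(vm), K, 10), target)
    (lp - lm) / (2 * h)
  })
  expect_lt(max(abs(res$grad - fd)) / max(abs(fd)), 5e-2)
})

test_that("mask PNG IO round-trips binary masks bit-exactly", {
  K <- test_K()
  m <- rasterize_hard(cube_fixture(1), cube_pose(), K)
  p <- file.path(tempdir(), "m.png")
  write_mask_png(m, p)
  m2 <- read_mask_png(p, "binary")
  expect_identical(as.integer(m2), as.integer(m))
})
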