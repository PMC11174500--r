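test_that("pose sampling is deterministic and matches uniform-SO(3) statistics", {
  rg <- pose_sampling_ranges(depth = c(3, 5))
  a <- sample_poses(rg, 5, seed = 42)
  b <- sample_poses(rg, 5, seed = 42)
  expect_identical(lapply(a, unclass), lapply(b, unclass))

  ps <- sample_poses(rg, 20000, seed = 7)
  ang <- vapply(ps, function(p) rotation_geodesic_deg(pose6d(), p), 0.0)
  # mean rotation angle of uniform SO(3): integral of theta (1-cos)/pi
  expect_lt(abs(mean(ang) - (pi / 2 + 2 / pi) * 180 / pi), 1)
  zs <- vapply(ps, function(p) p$t[3], 0.0)
  expect_lt(abs(mean(zs) - 4), 0.02)
  # lateral offsets stay within the configured fraction of depth
  xs <- vapply(ps, function(p) p$t[1] / p$t[3], 0.0)
  expect_true(all(xs >= -0.3 & xs <= 0.3))
})

test_that("Euler-interval rotation sampling respects the given ranges", {
  rg <- pose_sampling_ranges(rotation = list(rx = c(-10, 10), ry = c(0, 0),
                                             rz = c(0, 0)),
                             depth = c(4, 4))
  ps <- sample_poses(rg, 200, seed = 3)
  ang <- vapply(ps, function(p) rotation_geodesic_deg(pose6d(), p), 0.0)
  expect_true(all(ang <= 10 + 1e-9))
})

test_that("heatmap ground truth follows the Gaussian closed form", {
  K <- test_K640()
  hm <- make_heatmap_gt(matrix(c(160, 120), 1), K, sigma = 8, stride = 4L)
  expect_equal(dim(hm), c(120, 160, 1))
  # keypoint on a grid point: peak exactly 1 at that cell
  expect_equal(hm[31, 41, 1], 1)
  expect_equal(max(hm), 1)
  # value at 8 px image distance: exp(-0.5)
  expect_equal(hm[31, 43, 1], exp(-0.5), tolerance = 1e-12)
  # mass: sum ~ 2 pi sigma^2 / stride^2 away from borders
  expect_lt(abs(sum(hm) * 16 / (2 * pi * 64) - 1), 0.01)
  # invisible keypoints get zero maps
  pr <- structure(list(uv = matrix(c(160, 120, NA, NA), 2, byrow = TRUE),
                       visible = c(TRUE, FALSE)), class = "projections2d")
  hm2 <- make_heatmap_gt(pr, K, 8, 4L)
  expect_true(all(hm2[, , 2] == 0))
})

test_that("soft-argmax recovers ground-truth peaks to sub-pixel accuracy", {
  K <- test_K640()
  # at a grid point: exact to 0.5 px
  hm <- make_heatmap_gt(matrix(c(160, 120), 1), K, 8, 4L)
  est <- regress_coordinates(hm)
  expect_lt(max(abs(est$uv - c(160, 120))), 0.5)
  # interior keypoints at arbitrary sub-grid positions
  set.seed(12)
  for (i in 1:20) {
    uv <- matrix(c(runif(1, 100, 540), runif(1, 100, 380)), 1)
    est <- regress_coordinates(make_heatmap_gt(uv, K, 8, 4L))
    expect_lt(sqrt(sum((est$uv - uv)^2)), 0.5)
  }
  # two equal mirror peaks: midpoint (documented behavior)
  m <- array(0, c(10, 10, 1))
  m[3, 3, 1] <- 1; m[9, 9, 1] <- 1
  est <- regress_coordinates(structure(m, stride = 1L, class = c("heatmap", "array")))
  expect_equal(as.numeric(est$uv), c(5, 5))
  # all-zero map flagged invisible
  est0 <- regress_coordinates(array(0, c(10, 10, 1)), stride = 1L)
  expect_false(est0$visible[1])
  # random unimodal maps vs brute-force weighted mean
  set.seed(13)
  for (i in 1:5) {
    uv <- matrix(c(runif(1, 80, 560), runif(1, 80, 400)), 1)
    hm <- make_heatmap_gt(uv, K, 8, 4L)
    est <- regress_coordinates(hm, tau = 25)
    w <- exp(25 * (hm[, , 1] - max(hm)))
    w <- w / sum(w)
    gu <- (seq_len(160) - 1) * 4; gv <- (seq_len(120) - 1) * 4
    oracle <- c(sum(colSums(w) * gu), sum(rowSums(w) * gv))
    expect_lt(max(abs(est$uv - oracle)), 1e-9)
  }
})

test_that("noise model obeys its contracts", {
  m0 <- mask_image(matrix(0L, 100, 100), "binary")
  # all components off: identity
  clean <- add_noise(m0, noise_config(0, 0, 0, 0), seed = 5)
  expect_identical(as.integer(clean), as.integer(m0))
  # salt-and-pepper at q = 0.01 on all-zero 100x100: 100 +- 30 flips
  nz <- add_noise(m0, noise_config(flip_rate = 0.01, morph_radius = 0,
                                   n_blobs = 0), seed = 6)
  expect_true(abs(sum(nz) - 100) <= 30)
  expect_true(all(nz %in% c(0L, 1L)))
  expect_error(noise_config(flip_rate = 2), "flip_rate")
  # default noise keeps IOU high on the cube silhouette at the dataset
  # resolution (magnitudes are calibrated for 640x480 masks)
  K <- test_K640()
  mask <- rasterize_hard(cube_fixture(1),
                         pose6d(rotation = c(0.3, 0.2, 0.1),
                                translation = c(0.1, -0.05, 6)), K)
  noisy <- add_noise(mask, noise_config(), seed = 7)
  expect_gte(iou(noisy, mask), 0.85)
  # seeded: reproducible
  noisy2 <- add_noise(mask, noise_config(), seed = 7)
  expect_identical(as.integer(noisy), as.integer(noisy2))
})

test_that("generated datasets satisfy every record invariant", {
  mesh <- toy_instrument("hook")
  K <- tiny_camera()
  dir1 <- file.path(tempdir(), "ds_a")
  unlink(dir1, recursive = TRUE)
  manifest <- generate_dataset(mesh, K, default_pose_ranges(mesh), n = 10,
                               seed = 99, out_dir = dir1)
  expect_length(manifest$samples, 10)
  kp <- manifest$header$keypoints3d
  n_vis <- integer(0)
  for (i in 1:10) {
    s <- load_sample(manifest, i, noisy = FALSE)
    # stored projections re-verified against the stored pose
    proj <- project_points(kp, s$pose, K)
    expect_lt(max(abs(proj$uv - s$uv), na.rm = TRUE), 1e-6)
    expect_equal(proj$visible, s$visible)
    # mask reproduced bit-exactly by the rasterizer
    m <- rasterize_hard(mesh, s$pose, K)
    expect_identical(as.integer(s$mask), as.integer(m))
    expect_gt(sum(s$mask), 0)
    n_vis <- c(n_vis, sum(s$visible))
  }
  expect_gte(mean(n_vis >= 6), 0.9)
})

test_that("dataset generation is byte-identical across runs with one seed", {
  mesh <- cube_fixture(1)
  K <- test_K()
  d1 <- file.path(tempdir(), "ds_b1"); d2 <- file.path(tempdir(), "ds_b2")
  unlink(c(d1, d2), recursive = TRUE)
  generate_dataset(mesh, K, default_pose_ranges(mesh), n = 5, seed = 123,
                   out_dir = d1)
  generate_dataset(mesh, K, default_pose_ranges(mesh), n = 5, seed = 123,
                   out_dir = d2)
  expect_identical(readLines(file.path(d1, "manifest.jsonl")),
                   readLines(file.path(d2, "manifest.jsonl")))
  h1 <- tools::md5sum(sort(list.files(file.path(d1, "masks"), full.names = TRUE)))
  h2 <- tools::md5sum(sort(list.files(file.path(d2, "masks"), full.names = TRUE)))
  expect_identical(unname(h1), unname(h2))
})

test_that("heatmap and final losses follow their arithmetic", {
  m <- array(runif(60), c(5, 4, 3))
  expect_equal(heatmap_loss(m, m), 0)
  expect_equal(heatmap_loss(m + 0.1, m), 0.01, tolerance = 1e-12)
  expect_equal(heatmap_loss(m, m + 0.1), heatmap_loss(m + 0.1, m))
  expect_error(heatmap_loss(m, array(0, c(4, 4, 3))), "shapes")
  # 1 + 0.00005 * 2 + 1.2 * 3
  expect_equal(final_loss(1, 2, 3, loss_weights()), 4.6001)
  expect_equal(final_loss(1, 2, 3, loss_weights(alpha = 0, beta = 0)), 1)
  expect_equal(final_loss(0, 0, 0, loss_weights()), 0)
})
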