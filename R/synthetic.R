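#' Pose sampling ranges
#'
#' The "reasonable range" of SE(3) used by the synthetic-data generator,
#' made explicit and configurable. Defaults: rotations uniform over SO(3)
#' (via uniformly distributed unit quaternions); depth `Z` uniform in
#' `[3, 8]` mesh diameters; lateral translation `x, y` uniform in
#' `[-0.3, 0.3] * Z`, which keeps the object inside a 640x480 frame with the
#' default intrinsics.
#'
#' @param rotation Either `"uniform_so3"` or a named list of per-axis Euler
#'   intervals in degrees, e.g. `list(rx = c(-30, 30), ry = c(0, 0),
#'   rz = c(-180, 180))` (applied as `Rz Ry Rx`).
#' @param depth Length-2 depth interval `[Zmin, Zmax]` in model units;
#'   `Zmin > 0`.
#' @param xy_frac Length-2 interval: lateral offsets are drawn uniformly in
#'   `xy_frac * Z`.
#' @return A `pose_sampling_ranges` object.
#' @export
pose_sampling_ranges <- function(rotation = "uniform_so3",
                                 depth = c(3, 8),
                                 xy_frac = c(-0.3, 0.3)) {
  stopifnot(length(depth) == 2, depth[1] > 0, depth[2] >= depth[1],
            length(xy_frac) == 2, xy_frac[2] >= xy_frac[1])
  if (!identical(rotation, "uniform_so3")) {
    stopifnot(is.list(rotation), all(c("rx", "ry", "rz") %in% names(rotation)))
  }
  structure(list(rotation = rotation, depth = as.numeric(depth),
                 xy_frac = as.numeric(xy_frac)),
            class = "pose_sampling_ranges")
}

#' Default pose ranges for a mesh
#'
#' Expresses the default depth interval (3 to 8 mesh diameters) in model
#' units for a given mesh.
#'
#' @param mesh A `tri_mesh`.
#' @param depth_diameters Depth interval in units of the mesh diameter.
#' @inheritParams pose_sampling_ranges
#' @return A `pose_sampling_ranges` object.
#' @export
default_pose_ranges <- function(mesh, depth_diameters = c(3, 8),
                                rotation = "uniform_so3",
                                xy_frac = c(-0.3, 0.3)) {
  d <- mesh_diameter(mesh)
  pose_sampling_ranges(rotation = rotation, depth = depth_diameters * d,
                       xy_frac = xy_frac)
}

#' Sample poses uniformly from configured SE(3) ranges
#'
#' Rotations are uniform over SO(3) (normalized 4-vector of iid normals) or
#' uniform per Euler axis if intervals were given; depth is uniform in the
#' configured interval and lateral translation uniform in `xy_frac * Z`.
#' Deterministic for a fixed seed.
#'
#' @param ranges A [pose_sampling_ranges()] object.
#' @param n Number of poses.
#' @param seed Integer seed.
#' @return A list of `pose6d`.
#' @export
sample_poses <- function(ranges, n, seed) {
  stopifnot(inherits(ranges, "pose_sampling_ranges"), n >= 1)
  old <- local_seed(seed)
  on.exit(restore_seed(old))
  lapply(seq_len(n), function(i) sample_pose_one(ranges))
}

sample_pose_one <- function(ranges) {
  R <- if (identical(ranges$rotation, "uniform_so3")) {
    q <- rnorm(4)
    rotmat_from_quat(q / sqrt(sum(q^2)))
  } else {
    rr <- ranges$rotation
    ang <- vapply(c("rx", "ry", "rz"),
                  function(a) runif(1, rr[[a]][1], rr[[a]][2]) * pi / 180,
                  0.0)
    rotmat_from_axis_angle(c(0, 0, ang[3])) %*%
      rotmat_from_axis_angle(c(0, ang[2], 0)) %*%
      rotmat_from_axis_angle(c(ang[1], 0, 0))
  }
  z <- runif(1, ranges$depth[1], ranges$depth[2])
  x <- runif(1, ranges$xy_frac[1], ranges$xy_frac[2]) * z
  y <- runif(1, ranges$xy_frac[1], ranges$xy_frac[2]) * z
  pose6d(R, c(x, y, z))
}

#' Segmentation-noise configuration
#'
#' Emulates imperfections of an upstream segmentation network on binary
#' masks: boundary erosion/dilation by up to `morph_radius` px,
#' salt-and-pepper pixel flips at rate `flip_rate`, and random disc-shaped
#' holes/blobs. Every component can be switched off; all draws are seeded.
#' Defaults are calibrated to keep IOU(noisy, clean) around 0.9 on typical
#' silhouettes.
#'
#' @param flip_rate Per-pixel flip probability in `[0, 1]`.
#' @param morph_radius Maximum erosion/dilation radius in px (0 disables).
#' @param n_blobs Maximum number of disc speckles (holes on foreground,
#'   blobs on background); 0 disables.
#' @param blob_radius Maximum speckle radius in px.
#' @return A `noise_config` object.
#' @export
noise_config <- function(flip_rate = 0.002, morph_radius = 1L,
                         n_blobs = 2L, blob_radius = 4) {
  if (flip_rate < 0 || flip_rate > 1) stop("flip_rate must be in [0, 1]")
  stopifnot(morph_radius >= 0, n_blobs >= 0, blob_radius >= 0)
  structure(list(flip_rate = flip_rate, morph_radius = as.integer(morph_radius),
                 n_blobs = as.integer(n_blobs), blob_radius = blob_radius),
            class = "noise_config")
}

#' Add segmentation-style noise to a binary mask
#'
#' @param mask A binary `mask_image`.
#' @param params A [noise_config()].
#' @param seed Integer seed.
#' @return A binary `mask_image` of the same shape.
#' @export
add_noise <- function(mask, params = noise_config(), seed = 1L) {
  if (!identical(mask_mode(mask), "binary")) stop("add_noise expects a binary mask")
  m <- matrix(as.integer(mask), nrow(mask), ncol(mask))
  old <- local_seed(seed)
  on.exit(restore_seed(old))
  # 1. boundary erosion/dilation
  if (params$morph_radius > 0 && any(m == 1L)) {
    r <- sample.int(params$morph_radius, 1)
    op <- sample(c("erode", "dilate"), 1)
    m <- binary_morph(m, r, op)
  }
  # 2. disc speckles: holes on foreground, blobs near the silhouette
  if (params$n_blobs > 0 && params$blob_radius > 0) {
    nb <- sample.int(params$n_blobs + 1L, 1) - 1L
    fg <- which(m == 1L)
    for (b in seq_len(nb)) {
      if (length(fg) == 0) break
      center <- arrayInd(fg[sample.int(length(fg), 1)], dim(m))
      jitter <- round(runif(2, -params$blob_radius, params$blob_radius))
      rad <- runif(1, 1, params$blob_radius)
      val <- sample(c(0L, 1L), 1)
      m <- paint_disc(m, center[1] + jitter[1], center[2] + jitter[2], rad, val)
    }
  }
  # 3. salt-and-pepper flips
  if (params$flip_rate > 0) {
    flip <- runif(length(m)) < params$flip_rate
    m[flip] <- 1L - m[flip]
  }
  mask_image(m, "binary")
}

binary_morph <- function(m, radius, op = c("erode", "dilate")) {
  op <- match.arg(op)
  if (requireNamespace("EBImage", quietly = TRUE)) {
    brush <- EBImage::makeBrush(2L * radius + 1L, shape = "disc")
    out <- if (op == "erode") EBImage::erode(m, brush) else EBImage::dilate(m, brush)
    return(matrix(as.integer(out > 0.5), nrow(m), ncol(m)))
  }
  # fallback: separable square structuring element
  for (k in seq_len(radius)) {
    shifted <- list(
      rbind(m[-1, , drop = FALSE], m[nrow(m), ]),
      rbind(m[1, ], m[-nrow(m), , drop = FALSE]),
      cbind(m[, -1, drop = FALSE], m[, ncol(m)]),
      cbind(m[, 1], m[, -ncol(m), drop = FALSE])
    )
    agg <- Reduce(`+`, shifted) + m
    m <- if (op == "erode") (agg == 5L) + 0L else (agg > 0L) + 0L
  }
  m
}

paint_disc <- function(m, row, col, radius, value) {
  r0 <- max(1, floor(row - radius)); r1 <- min(nrow(m), ceiling(row + radius))
  c0 <- max(1, floor(col - radius)); c1 <- min(ncol(m), ceiling(col + radius))
  if (r0 > r1 || c0 > c1) return(m)
  rr <- r0:r1; cc <- c0:c1
  d2 <- outer((rr - row)^2, (cc - col)^2, "+")
  sub <- m[rr, cc, drop = FALSE]
  sub[d2 <= radius^2] <- value
  m[rr, cc] <- sub
  m
}

#' Generate a synthetic silhouette training dataset
#'
#' Renders `n` samples of the mesh under poses drawn from `ranges`: each
#' sample gets a clean binary mask PNG (plus a noisy variant when `noise` is
#' given), the pose label, the farthest-point 3D keypoints, and their 2D
#' projections, recorded in a JSON-lines manifest (`manifest.jsonl`; first
#' line is a versioned header). Poses whose silhouette is empty are
#' resampled (count reported in the header). Generation is deterministic per
#' `(seed, index)`, so runs with the same seed produce byte-identical
#' manifests.
#'
#' @param mesh A `tri_mesh`.
#' @param K A `camera_intrinsics`.
#' @param ranges A [pose_sampling_ranges()]; default [default_pose_ranges()].
#' @param n Number of samples.
#' @param seed Integer seed.
#' @param out_dir Output directory (created if missing).
#' @param noise A [noise_config()] or `NULL` to disable augmentation.
#' @param keypoints A `feature_points3d`; default: 8 farthest-point-sampled
#'   vertices.
#' @param sigma,stride Heatmap ground-truth parameters recorded in the
#'   header (maps themselves are built on the fly by [load_sample()]).
#' @param instrument_id Label stored with every record.
#' @return The manifest, invisibly (as returned by [read_manifest()]).
#' @export
generate_dataset <- function(mesh, K, ranges = default_pose_ranges(mesh),
                             n, seed, out_dir, noise = noise_config(),
                             keypoints = NULL, sigma = 8, stride = 4L,
                             instrument_id = "instrument") {
  stopifnot(n >= 1)
  if (is.null(keypoints)) keypoints <- farthest_point_sampling(mesh, 8L)
  dir.create(file.path(out_dir, "masks"), recursive = TRUE, showWarnings = FALSE)
  resampled <- 0L
  lines <- character(n)
  for (i in seq_len(n)) {
    rec_seed <- sub_seed(seed, i)
    old <- local_seed(rec_seed)
    pose <- NULL
    mask <- NULL
    for (try in 1:100) {
      cand <- sample_pose_one(ranges)
      m <- suppressWarnings(rasterize_hard(mesh, cand, K))
      if (any(m == 1L)) { pose <- cand; mask <- m; break }
      resampled <- resampled + 1L
    }
    if (is.null(pose)) {
      restore_seed(old)
      stop("could not draw a paintable pose for sample ", i)
    }
    noisy_rel <- NULL
    if (!is.null(noise)) {
      noisy <- add_noise(mask, noise, seed = sub_seed(rec_seed, 7919L))
      noisy_rel <- file.path("masks", sprintf("mask_%05d_noisy.png", i))
      write_mask_png(noisy, file.path(out_dir, noisy_rel))
    }
    restore_seed(old)
    mask_rel <- file.path("masks", sprintf("mask_%05d.png", i))
    write_mask_png(mask, file.path(out_dir, mask_rel))
    proj <- project_points(keypoints, pose, K)
    rec <- list(
      index = i, rng_seed = rec_seed, instrument_id = instrument_id,
      pose = pose_to_record(pose),
      keypoints2d = list(uv = round(proj$uv, 9), visible = proj$visible),
      mask = mask_rel
    )
    if (!is.null(noisy_rel)) rec$mask_noisy <- noisy_rel
    lines[i] <- jsonlite::toJSON(rec, auto_unbox = TRUE, digits = NA,
                                 na = "null")
  }
  header <- list(
    schema_version = 1L, n = n, seed = seed,
    instrument_id = instrument_id,
    intrinsics = list(fx = K$fx, fy = K$fy, cx = K$cx, cy = K$cy,
                      width = K$width, height = K$height),
    keypoints3d = keypoints$points,
    keypoint_index = keypoints$index,
    sigma = sigma, stride = stride,
    resampled_empty = resampled
  )
  writeLines(c(jsonlite::toJSON(header, auto_unbox = TRUE, digits = NA),
               lines),
             file.path(out_dir, "manifest.jsonl"))
  if (resampled > 0) {
    message(resampled, " empty-silhouette pose draws were resampled")
  }
  invisible(read_manifest(out_dir))
}

#' Read a dataset manifest
#'
#' @param dir Dataset directory containing `manifest.jsonl`.
#' @return A `pose_manifest`: list with `header`, `samples` (list of
#'   records) and `dir`.
#' @export
read_manifest <- function(dir) {
  path <- file.path(dir, "manifest.jsonl")
  lines <- readLines(path, warn = FALSE)
  header <- jsonlite::fromJSON(lines[1], simplifyVector = TRUE)
  header$keypoints3d <- matrix(unlist(header$keypoints3d),
                               ncol = 3, byrow = FALSE)
  samples <- lapply(lines[-1], function(ln) {
    rec <- jsonlite::fromJSON(ln, simplifyVector = TRUE)
    rec$keypoints2d$uv <- matrix(unlist(rec$keypoints2d$uv), ncol = 2)
    rec
  })
  structure(list(header = header, samples = samples, dir = dir),
            class = "pose_manifest")
}

#' @export
print.pose_manifest <- function(x, ...) {
  cat(sprintf("pose_manifest: %d samples of '%s' (%dx%d masks)\n",
              length(x$samples), x$header$instrument_id,
              x$header$intrinsics$width, x$header$intrinsics$height))
  invisible(x)
}

#' Load one sample from a manifest
#'
#' @param manifest A `pose_manifest`.
#' @param i Sample index.
#' @param noisy Load the noise-augmented mask when available?
#' @param heatmaps Also build the Gaussian ground-truth heatmaps?
#' @return List with `mask`, `pose`, `uv`, `visible` and optionally
#'   `heatmap`.
#' @export
load_sample <- function(manifest, i, noisy = TRUE, heatmaps = FALSE) {
  rec <- manifest$samples[[i]]
  hd <- manifest$header
  K <- camera_intrinsics(hd$intrinsics$fx, hd$intrinsics$fy,
                         hd$intrinsics$cx, hd$intrinsics$cy,
                         hd$intrinsics$width, hd$intrinsics$height)
  rel <- if (noisy && !is.null(rec$mask_noisy)) rec$mask_noisy else rec$mask
  out <- list(
    mask = read_mask_png(file.path(manifest$dir, rel), "binary"),
    clean_mask_path = file.path(manifest$dir, rec$mask),
    pose = pose_from_record(rec$pose),
    uv = rec$keypoints2d$uv,
    visible = rec$keypoints2d$visible,
    K = K
  )
  if (heatmaps) {
    proj <- structure(list(uv = out$uv, visible = out$visible),
                      class = "projections2d")
    out$heatmap <- make_heatmap_gt(proj, K, sigma = hd$sigma,
                                   stride = hd$stride)
  }
  out
}

# --- seeding helpers --------------------------------------------------------

# derive a deterministic 31-bit sub-seed from (seed, index)
sub_seed <- function(seed, index) {
  as.integer((as.double(seed %% 48611L) * 42793 + as.double(index) * 69621 +
                13) %% 2147483647)
}

local_seed <- function(seed) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  set.seed(seed)
  old
}

restore_seed <- function(old) {
  if (is.null(old)) {
    rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
  invisible(NULL)
}
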