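#' Built-in parametric toy meshes
#'
#' Simple parametric shapes standing in for reconstructed instrument models:
#' an axis-aligned cube, and three toy instruments (plain tube,
#' cylinder-with-hook, cylinder-with-jaws) whose long thin silhouettes mimic
#' laparoscopic tools. All are synthetic stand-ins, not reconstructions of
#' real instruments. Units are arbitrary model units.
#'
#' @param side Cube edge length.
#' @param center Cube center (length 3).
#' @return A `tri_mesh`.
#' @export
cube_mesh <- function(side = 1, center = c(0, 0, 0)) {
  h <- side / 2
  v <- as.matrix(expand.grid(x = c(-h, h), y = c(-h, h), z = c(-h, h)))
  v <- sweep(v, 2, center, "+")
  f <- rbind(
    c(1, 3, 2), c(2, 3, 4),  # z = -h
    c(5, 6, 7), c(6, 8, 7),  # z = +h
    c(1, 2, 5), c(2, 6, 5),  # y = -h
    c(3, 7, 4), c(4, 7, 8),  # y = +h
    c(1, 5, 3), c(3, 5, 7),  # x = -h
    c(2, 4, 6), c(4, 8, 6)   # x = +h
  )
  tri_mesh(v, f)
}

# closed cylinder from p0 to p1; returns list(vertices, faces) with 1-based
# faces, for concatenation
make_cylinder <- function(p0, p1, radius, n_seg = 12L, n_rings = 2L) {
  axis <- p1 - p0
  len <- sqrt(sum(axis^2))
  az <- axis / len
  ref <- if (abs(az[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  ax <- crossv(az, ref); ax <- ax / sqrt(sum(ax^2))
  ay <- crossv(az, ax)
  ang <- 2 * pi * (seq_len(n_seg) - 1) / n_seg
  ring <- cbind(cos(ang), sin(ang)) %*% rbind(ax, ay) * radius
  ts <- seq(0, 1, length.out = n_rings + 1)
  verts <- do.call(rbind, lapply(ts, function(s) {
    sweep(ring, 2, p0 + s * len * az, "+")
  }))
  faces <- list()
  for (r in seq_len(n_rings)) {
    base0 <- (r - 1) * n_seg
    base1 <- r * n_seg
    for (i in seq_len(n_seg)) {
      j <- i %% n_seg + 1
      faces[[length(faces) + 1]] <- c(base0 + i, base0 + j, base1 + i)
      faces[[length(faces) + 1]] <- c(base0 + j, base1 + j, base1 + i)
    }
  }
  # end caps (fan to centers)
  c0 <- nrow(verts) + 1; c1 <- nrow(verts) + 2
  verts <- rbind(verts, p0, p0 + len * az)
  topbase <- n_rings * n_seg
  for (i in seq_len(n_seg)) {
    j <- i %% n_seg + 1
    faces[[length(faces) + 1]] <- c(c0, j, i)
    faces[[length(faces) + 1]] <- c(c1, topbase + i, topbase + j)
  }
  list(vertices = verts, faces = do.call(rbind, faces))
}

merge_mesh_parts <- function(...) {
  parts <- list(...)
  verts <- NULL
  faces <- NULL
  off <- 0L
  for (p in parts) {
    verts <- rbind(verts, p$vertices)
    faces <- rbind(faces, p$faces + off)
    off <- off + nrow(p$vertices)
  }
  tri_mesh(verts, faces)
}

#' @rdname cube_mesh
#' @param type One of `"tube"`, `"hook"`, `"jaws"`.
#' @param length Shaft length in model units.
#' @param radius Shaft radius in model units.
#' @param n_seg Cross-section segments (controls face count).
#' @export
toy_instrument <- function(type = c("tube", "hook", "jaws"),
                           length = 10, radius = 0.4, n_seg = 12L) {
  type <- match.arg(type)
  shaft <- make_cylinder(c(0, 0, 0), c(0, 0, length), radius,
                         n_seg = n_seg, n_rings = 3L)
  if (type == "tube") {
    return(merge_mesh_parts(shaft))
  }
  if (type == "hook") {
    # bent tip curving out of the shaft plane: keeps the farthest-point
    # keypoints non-coplanar, as on a real curved hook electrode
    r2 <- radius * 0.6
    tip <- c(0, 0, length)
    seg1 <- make_cylinder(tip, tip + c(0.3, 0.5, 0.8), r2, n_seg, 1L)
    seg2 <- make_cylinder(tip + c(0.3, 0.5, 0.8), tip + c(0.8, 1.2, 1.0),
                          r2, n_seg, 1L)
    seg3 <- make_cylinder(tip + c(0.8, 1.2, 1.0), tip + c(1.5, 1.7, 0.6),
                          r2 * 0.8, n_seg, 1L)
    return(merge_mesh_parts(shaft, seg1, seg2, seg3))
  }
  # jaws: two diverging thin cylinders at the tip (slightly asymmetric so
  # the silhouette disambiguates mirror poses)
  r2 <- radius * 0.5
  tip <- c(0, 0, length)
  jaw1 <- make_cylinder(tip, tip + c(0.9, 0.25, 1.8), r2, n_seg, 1L)
  jaw2 <- make_cylinder(tip, tip + c(-0.7, -0.45, 1.6), r2, n_seg, 1L)
  merge_mesh_parts(shaft, jaw1, jaw2)
}
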