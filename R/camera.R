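#' Pinhole camera intrinsics
#'
#' Constructs a validated set of pinhole camera parameters. The camera model
#' has zero skew and no lens distortion; pixel coordinates are 0-based with
#' pixel centers at integer coordinates, `u` running along the image width.
#'
#' @param fx,fy Focal lengths in pixels (must be positive).
#' @param cx,cy Principal point in pixels; `0 <= cx < width`,
#'   `0 <= cy < height`.
#' @param width,height Image size in pixels.
#' @return An object of class `camera_intrinsics`.
#' @examples
#' K <- camera_intrinsics(fx = 100, fy = 100, cx = 320, cy = 240,
#'                        width = 640, height = 480)
#' intrinsics_matrix(K)
#' @export
camera_intrinsics <- function(fx, fy, cx, cy, width, height) {
  stopifnot(
    is.numeric(fx), is.numeric(fy), fx > 0, fy > 0,
    is.numeric(width), is.numeric(height), width >= 1, height >= 1
  )
  if (cx < 0 || cx >= width || cy < 0 || cy >= height) {
    stop("principal point (cx, cy) must lie inside the image")
  }
  structure(
    list(fx = as.numeric(fx), fy = as.numeric(fy),
         cx = as.numeric(cx), cy = as.numeric(cy),
         width = as.integer(width), height = as.integer(height)),
    class = "camera_intrinsics"
  )
}

#' @export
print.camera_intrinsics <- function(x, ...) {
  cat(sprintf("camera_intrinsics: fx=%g fy=%g cx=%g cy=%g  image %dx%d\n",
              x$fx, x$fy, x$cx, x$cy, x$width, x$height))
  invisible(x)
}

#' 3x3 intrinsic matrix K
#'
#' @param K A `camera_intrinsics` object.
#' @return The 3x3 upper-triangular intrinsic matrix.
#' @export
intrinsics_matrix <- function(K) {
  stopifnot(inherits(K, "camera_intrinsics"))
  matrix(c(K$fx, 0, 0,
           0, K$fy, 0,
           K$cx, K$cy, 1), 3, 3)
}

#' Read / write camera intrinsics
#'
#' Intrinsics are interchanged as a flat YAML or JSON block with fields
#' `fx, fy, cx, cy, width, height` (format chosen by file extension).
#'
#' @param path File path ending in `.yaml`, `.yml` or `.json`.
#' @return `read_intrinsics` returns a `camera_intrinsics` object;
#'   `write_intrinsics` returns `path` invisibly.
#' @export
read_intrinsics <- function(path) {
  ext <- tolower(tools::file_ext(path))
  vals <- if (ext %in% c("yaml", "yml")) {
    yaml::read_yaml(path)
  } else if (ext == "json") {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    stop("unsupported intrinsics format: .", ext)
  }
  need <- c("fx", "fy", "cx", "cy", "width", "height")
  if (!all(need %in% names(vals))) {
    stop("intrinsics file missing fields: ",
         paste(setdiff(need, names(vals)), collapse = ", "))
  }
  camera_intrinsics(vals$fx, vals$fy, vals$cx, vals$cy, vals$width, vals$height)
}

#' @rdname read_intrinsics
#' @param K A `camera_intrinsics` object to serialize.
#' @export
write_intrinsics <- function(K, path) {
  stopifnot(inherits(K, "camera_intrinsics"))
  vals <- list(fx = K$fx, fy = K$fy, cx = K$cx, cy = K$cy,
               width = K$width, height = K$height)
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("yaml", "yml")) {
    yaml::write_yaml(vals, path)
  } else if (ext == "json") {
    jsonlite::write_json(vals, path, auto_unbox = TRUE, digits = NA)
  } else {
    stop("unsupported intrinsics format: .", ext)
  }
  invisible(path)
}

#' Default endoscope-like intrinsics
#'
#' A 640x480 pinhole camera with focal length 525 px, the resolution all
#' dataset masks are rendered at by default.
#'
#' @param width,height Image size in pixels.
#' @param f Focal length in pixels (applied to both axes).
#' @return A `camera_intrinsics` object.
#' @export
default_intrinsics <- function(width = 640L, height = 480L, f = 525) {
  camera_intrinsics(fx = f, fy = f, cx = width / 2, cy = height / 2,
                    width = width, height = height)
}

#' Rescale intrinsics to a new image resolution
#'
#' Scales focal lengths and principal point by the resolution ratio; useful
#' for training/refining at reduced resolution.
#'
#' @param K A `camera_intrinsics` object.
#' @param width,height Target resolution in pixels.
#' @return A `camera_intrinsics` at the new resolution.
#' @export
scale_intrinsics <- function(K, width, height) {
  sx <- width / K$width
  sy <- height / K$height
  camera_intrinsics(K$fx * sx, K$fy * sy, K$cx * sx, K$cy * sy, width, height)
}
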