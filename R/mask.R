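#' Mask images
#'
#' A mask image is a `height x width` matrix: binary mode holds 0/1 integers
#' (segmentation / hard silhouettes), soft mode holds values in [0, 1]
#' (differentiable renderings). Losses always use the float buffers; PNG
#' files are an 8-bit interchange format only.
#'
#' @param m A numeric or integer matrix.
#' @param mode `"binary"` or `"soft"`.
#' @return The matrix with class `mask_image` and attribute `mode`.
#' @export
mask_image <- function(m, mode = c("binary", "soft")) {
  mode <- match.arg(mode)
  stopifnot(is.matrix(m))
  if (mode == "binary") {
    storage.mode(m) <- "integer"
    if (!all(m %in% c(0L, 1L))) stop("binary mask must contain only 0/1")
  } else {
    storage.mode(m) <- "double"
    m[m < 0] <- 0
    m[m > 1] <- 1
  }
  structure(m, mode = mode, class = c("mask_image", class(m)))
}

mask_mode <- function(m) attr(m, "mode") %||% "binary"

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read and write masks as PNG
#'
#' Binary masks are written as 8-bit grayscale 0/255; soft masks are
#' quantized to 8 bits (inspection only). Reading thresholds at 0.5 when
#' `mode = "binary"`.
#'
#' @param mask A `mask_image` or plain matrix.
#' @param path PNG file path.
#' @return `write_mask_png` returns `path` invisibly; `read_mask_png`
#'   returns a `mask_image`.
#' @export
write_mask_png <- function(mask, path) {
  png::writePNG(matrix(as.numeric(mask), nrow(mask), ncol(mask)), path)
  invisible(path)
}

#' @rdname write_mask_png
#' @param mode Mode of the mask being read.
#' @export
read_mask_png <- function(path, mode = c("binary", "soft")) {
  mode <- match.arg(mode)
  m <- png::readPNG(path)
  if (length(dim(m)) == 3) m <- m[, , 1]
  if (mode == "binary") m <- (m >= 0.5) + 0L
  mask_image(m, mode)
}
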