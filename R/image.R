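#' Image grids
#'
#' Images flow through the pipeline as plain numeric arrays of shape
#' `H x W x C` with integer intensities in `[0, 255]` and `C` either 1
#' (grayscale) or 3 (RGB). `image_grid()` validates and normalises an
#' array/matrix into that shape.
#'
#' @param pixels numeric matrix (`H x W`) or array (`H x W x C`) of
#'   intensities in `[0, 255]`.
#' @return a numeric `H x W x C` array of class `image_grid`.
#' @examples
#' img <- image_grid(matrix(0:24, 5, 5) * 10)
#' dim(img)
#' @export
image_grid <- function(pixels) {
  if (is.matrix(pixels)) pixels <- array(pixels, c(dim(pixels), 1L))
  if (!is.array(pixels) || length(dim(pixels)) != 3L)
    stopf("`pixels` must be an H x W x C array or an H x W matrix")
  d <- dim(pixels)
  if (d[1] < 1 || d[2] < 1) stopf("image must have positive height and width")
  if (!d[3] %in% c(1L, 3L)) stopf("channel count must be 1 or 3, got %d", d[3])
  if (anyNA(pixels) || any(pixels < 0) || any(pixels > 255))
    stopf("pixel values must lie in [0, 255]")
  storage.mode(pixels) <- "double"
  structure(pixels, class = c("image_grid", "array"))
}

#' @export
print.image_grid <- function(x, ...) {
  d <- dim(x)
  cat(sprintf("<image_grid %d x %d x %d, range [%g, %g]>\n",
              d[1], d[2], d[3], min(x), max(x)))
  invisible(x)
}

#' Read and write images as PNG
#'
#' Thin wrappers over the \pkg{png} package converting between files and
#' [image_grid()] arrays (intensities scaled to `[0, 255]` and rounded).
#'
#' @param path file path.
#' @return `read_image()` returns an `image_grid`; `write_image()` returns
#'   `path` invisibly.
#' @export
read_image <- function(path) {
  px <- png::readPNG(path)
  if (length(dim(px)) == 2L) px <- array(px, c(dim(px), 1L))
  if (dim(px)[3] == 4L) px <- px[, , 1:3, drop = FALSE]  # drop alpha
  if (dim(px)[3] == 2L) px <- px[, , 1L, drop = FALSE]   # gray + alpha
  image_grid(round(px * 255))
}

#' @rdname read_image
#' @param img an [image_grid()].
#' @export
write_image <- function(img, path) {
  img <- image_grid(img)
  px <- unclass(img) / 255
  if (dim(px)[3] == 1L) px <- px[, , 1L]
  png::writePNG(px, path)
  invisible(path)
}
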