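#' Grayscale image container
#'
#' `gray_image()` wraps a matrix of non-negative integer pixel intensities
#' together with its bit depth `m` (bits per pixel). All pipeline stages
#' consume and produce this container; pixel values must lie in
#' `[0, 2^m - 1]` and both image dimensions must be at least 2.
#'
#' @param pixels Integer or numeric matrix of intensities, row-major
#'   `(row, col)` indexing.
#' @param bit_depth Bits per pixel; the dynamic range is `[0, 2^bit_depth - 1]`.
#'   Default 8.
#' @return An object of class `gray_image` with fields `pixels` (integer
#'   matrix) and `bit_depth`.
#' @examples
#' img <- gray_image(matrix(0:255, 16, 16), bit_depth = 8)
#' img
#' @export
gray_image <- function(pixels, bit_depth = 8L) {
  if (!is.matrix(pixels) || !is.numeric(pixels))
    abort_validation("pixels must be a numeric matrix")
  if (nrow(pixels) < 2L || ncol(pixels) < 2L)
    abort_validation("image must be at least 2x2, got ",
                     nrow(pixels), "x", ncol(pixels))
  if (!is_count(bit_depth, min = 1L))
    abort_validation("bit_depth must be a positive integer")
  if (anyNA(pixels)) abort_validation("pixels contain NA")
  if (any(pixels != round(pixels)))
    abort_validation("pixels must be integer-valued")
  maxv <- 2^bit_depth - 1
  if (any(pixels < 0) || any(pixels > maxv))
    abort_validation("pixel values must lie in [0, ", maxv,
                     "] for bit_depth ", bit_depth)
  pixels <- matrix(as.integer(pixels), nrow(pixels), ncol(pixels))
  structure(list(pixels = pixels, bit_depth = as.integer(bit_depth)),
            class = "gray_image")
}

#' @export
print.gray_image <- function(x, ...) {
  cat(sprintf("<gray_image> %d x %d, %d-bit, intensity range [%d, %d]\n",
              nrow(x$pixels), ncol(x$pixels), x$bit_depth,
              min(x$pixels), max(x$pixels)))
  invisible(x)
}

#' @export
dim.gray_image <- function(x) dim(x$pixels)

#' @export
as.matrix.gray_image <- function(x, ...) x$pixels

is_gray_image <- function(x) inherits(x, "gray_image")

assert_gray_image <- function(x, arg = "img") {
  if (!is_gray_image(x)) abort_validation(arg, " must be a gray_image")
  invisible(x)
}

# min-max linear rescale of arbitrary non-negative intensities to 8 bits;
# a constant image maps to all-zero (degenerate range).
rescale_to_8bit <- function(values) {
  lo <- min(values); hi <- max(values)
  if (hi == lo) {
    out <- array(0L, dim = dim(values))
  } else {
    out <- round(255 * (values - lo) / (hi - lo))
  }
  storage.mode(out) <- "integer"
  out
}

#' Binary region mask
#'
#' A logical matrix marking a segmented region; shape always equals that of
#' the source image.
#'
#' @param cells Logical matrix (or 0/1 numeric matrix).
#' @return An object of class `binary_mask` (a logical matrix).
#' @examples
#' m <- binary_mask(matrix(c(TRUE, FALSE, FALSE, TRUE), 2, 2))
#' region_area(m)
#' @export
binary_mask <- function(cells) {
  if (!is.matrix(cells)) abort_validation("cells must be a matrix")
  if (is.numeric(cells)) {
    if (!all(cells %in% c(0, 1))) abort_validation("numeric mask must be 0/1")
    cells <- cells == 1
  }
  if (!is.logical(cells)) abort_validation("cells must be logical")
  if (anyNA(cells)) abort_validation("mask contains NA")
  structure(cells, class = c("binary_mask", "matrix", "array"))
}

#' @export
print.binary_mask <- function(x, ...) {
  cat(sprintf("<binary_mask> %d x %d, %d foreground px\n",
              nrow(x), ncol(x), sum(x)))
  invisible(x)
}

is_binary_mask <- function(x) inherits(x, "binary_mask")

as_mask <- function(m) binary_mask(m)
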