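#' Median-filter denoising
#'
#' Impulse-noise suppression with a square median filter; borders are
#' handled by edge replication so the output has the same shape and bit
#' depth as the input. `method = "none"` returns the input unchanged and
#' is provided so the preprocessing stage can be bypassed.
#'
#' @param img A [gray_image].
#' @param method `"median"` (default) or `"none"`.
#' @param window Odd window side length (default 3).
#' @return A [gray_image] of the same shape and bit depth.
#' @examples
#' img <- gray_image(matrix(0L, 5, 5)); img$pixels[3, 3] <- 255L
#' denoise(gray_image(img$pixels), window = 3)  # impulse removed
#' @export
denoise <- function(img, method = c("median", "none"), window = 3L) {
  assert_gray_image(img)
  method <- match.arg(method)
  if (method == "none") return(img)
  if (!is_count(window, min = 1L) || window %% 2L == 0L)
    abort_validation("window must be an odd positive integer, got ", window)
  px <- median_filter(img$pixels, as.integer(window))
  gray_image(px, img$bit_depth)
}

# square median filter with edge replication, vectorized as a stack of
# shifted copies with per-row median
median_filter <- function(m, w) {
  if (w == 1L) return(m)
  r <- nrow(m); cl <- ncol(m); h <- (w - 1L) %/% 2L
  ri <- pmin(pmax(seq_len(r + 2L * h) - h, 1L), r)
  ci <- pmin(pmax(seq_len(cl + 2L * h) - h, 1L), cl)
  pad <- m[ri, ci, drop = FALSE]
  stack <- matrix(0, r * cl, w * w)
  k <- 0L
  for (dr in 0:(w - 1L)) for (dc in 0:(w - 1L)) {
    k <- k + 1L
    stack[, k] <- pad[dr + seq_len(r), dc + seq_len(cl)]
  }
  out <- matrix(apply(stack, 1L, stats::median), r, cl)
  storage.mode(out) <- "integer"
  out
}

#' Mean squared error between two images
#'
#' `MSE = (1 / (P * Q)) * sum((f - fR)^2)` over all pixels of two images of
#' identical shape.
#'
#' @param original,processed [gray_image]s of identical shape.
#' @return Non-negative scalar.
#' @export
mse <- function(original, processed) {
  assert_gray_image(original, "original")
  assert_gray_image(processed, "processed")
  if (!identical(dim(original$pixels), dim(processed$pixels)))
    abort_validation("image shapes differ: ",
                     paste(dim(original$pixels), collapse = "x"), " vs ",
                     paste(dim(processed$pixels), collapse = "x"))
  d <- as.numeric(original$pixels) - as.numeric(processed$pixels)
  mean(d^2)
}

#' Peak signal-to-noise ratio
#'
#' Two variants are available. `as_printed` computes
#' `20 * log10((2^m - 1) / MSE)`; `standard` computes the conventional
#' `20 * log10((2^m - 1) / sqrt(MSE))`. Identical images (MSE = 0) return
#' `Inf`.
#'
#' @inheritParams mse
#' @param formula `"as_printed"` (default) or `"standard"`.
#' @return PSNR in decibels, `Inf` when the images are identical.
#' @export
psnr <- function(original, processed, formula = c("as_printed", "standard")) {
  formula <- match.arg(formula)
  assert_gray_image(original, "original")
  assert_gray_image(processed, "processed")
  if (original$bit_depth != processed$bit_depth)
    abort_validation("bit depths differ")
  e <- mse(original, processed)
  if (e == 0) return(Inf)
  peak <- 2^original$bit_depth - 1
  den <- if (formula == "as_printed") e else sqrt(e)
  20 * log10(peak / den)
}

#' Image quality and region-area report
#'
#' Bundles the fidelity metrics of a processed image against its original
#' with the pixel areas of the whole image and of a segmented region, in
#' the column order of the pipeline's quality CSV
#' (`image,psnr,mse,area_image_px,area_tumor_px`).
#'
#' @inheritParams psnr
#' @param mask Optional [binary_mask] of the segmented region.
#' @return A `quality_report` list: `mse`, `psnr_db`, `area_image_px`,
#'   `area_region_px`.
#' @export
quality_report <- function(original, processed, mask = NULL,
                           formula = c("as_printed", "standard")) {
  formula <- match.arg(formula)
  e <- mse(original, processed)
  p <- psnr(original, processed, formula)
  area_img <- length(original$pixels)
  area_reg <- if (is.null(mask)) 0L else region_area(mask)
  if (area_reg > area_img)
    abort_validation("region area exceeds image area")
  structure(list(mse = e, psnr_db = p,
                 area_image_px = as.integer(area_img),
                 area_region_px = as.integer(area_reg)),
            class = "quality_report")
}

#' @export
print.quality_report <- function(x, ...) {
  cat(sprintf(
    "<quality_report> PSNR %.2f dB | MSE %.4f | image %d px | region %d px\n",
    x$psnr_db, x$mse, x$area_image_px, x$area_region_px))
  invisible(x)
}
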