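test_that("8-bit PNG round-trips bit-exactly and infers dialect", {
  px <- matrix(c(0L, 255L, 255L, 0L), 2, 2)
  path <- withr::local_tempfile(fileext = ".png")
  save_image_png(gray_image(px), path)
  img <- load_image(path)
  expect_s3_class(img, "gray_image")
  expect_equal(img$bit_depth, 8L)
  expect_identical(img$pixels, px)
  expect_identical(load_image(path, "png")$pixels, px)
})

test_that("16-bit sources are min-max rescaled to 8 bits", {
  # constant 16-bit image: degenerate range maps to 0
  path <- withr::local_tempfile(fileext = ".tif")
  tiff::writeTIFF(matrix(4095 / 65535, 4, 4), path, bits.per.sample = 16L)
  expect_true(all(load_image(path)$pixels == 0L))

  # two-level 16-bit image maps onto the full 8-bit range
  m <- matrix(c(0, 4095, 4095, 0), 4, 4)
  tiff::writeTIFF(m / 65535, path, bits.per.sample = 16L)
  img <- load_image(path)
  expect_setequal(as.vector(img$pixels), c(0L, 255L))

  # gradient: matches the direct linear map round(255 (v-min)/(max-min))
  v <- matrix(seq(0L, 4095L, length.out = 64), 8, 8)
  v <- round(v)
  tif <- withr::local_tempfile(fileext = ".tif")
  tiff::writeTIFF(v / 65535, tif, bits.per.sample = 16L)
  img <- load_image(tif)
  expect_equal(img$pixels,
               matrix(as.integer(round(255 * (v - min(v)) /
                                         (max(v) - min(v)))), 8, 8))
})

test_that("color inputs are converted with standard luminance weights", {
  arr <- array(0, c(4, 4, 3))
  arr[, , 1] <- 1; arr[, , 2] <- 0.5; arr[, , 3] <- 0.25
  path <- withr::local_tempfile(fileext = ".png")
  png::writePNG(arr, path)
  img <- load_image(path)
  lum <- 0.299 * 255 + 0.587 * 127.5 + 0.114 * 63.75
  expect_true(all(abs(img$pixels - lum) <= 1))
})

test_that("DICOM fixtures parse under explicit and implicit VR", {
  px <- matrix(as.integer(round(seq(0, 4000, length.out = 48))), 6, 8)
  for (explicit in c(TRUE, FALSE)) {
    path <- withr::local_tempfile(fileext = ".dcm")
    write_test_dicom(path, px, bits_allocated = 16L, bits_stored = 12L,
                     explicit = explicit)
    img <- load_image(path, "dicom")
    expect_equal(dim(img$pixels), c(6L, 8L))
    # >8-bit source: min-max rescale oracle
    expect_equal(img$pixels,
                 matrix(as.integer(round(255 * (px - min(px)) /
                                           (max(px) - min(px)))), 6, 8))
  }
  # 8-bit DICOM keeps pixel values verbatim
  px8 <- matrix(sample(0:255, 24, TRUE), 4, 6)
  path <- withr::local_tempfile(fileext = ".dcm")
  write_test_dicom(path, px8, bits_allocated = 8L)
  expect_identical(load_image(path, "dicom")$pixels,
                   matrix(as.integer(px8), 4, 6))
})

test_that("multi-frame DICOM and unreadable files are rejected", {
  px <- matrix(1:12, 3, 4)
  path <- withr::local_tempfile(fileext = ".dcm")
  write_test_dicom(path, px, n_frames = 3L)
  expect_error(load_image(path, "dicom"), "multi-frame")
  bad <- withr::local_tempfile(fileext = ".png")
  writeLines("not an image", bad)
  expect_error(load_image(bad, "png"), "PNG")
  expect_error(load_image(file.path(tempdir(), "nope.png")), "not found")
})

test_that("median denoising removes impulses and matches the sorted oracle", {
  const <- gray_image(matrix(42L, 6, 6))
  expect_identical(denoise(const)$pixels, const$pixels)

  z <- matrix(0L, 5, 5); z[3, 3] <- 255L
  expect_true(all(denoise(gray_image(z), window = 3)$pixels == 0L))

  set.seed(101)
  img <- rand_gray(9, 9)
  expect_identical(denoise(img, window = 3)$pixels,
                   oracle_median(img$pixels, 3L))
  expect_identical(denoise(img, window = 5)$pixels,
                   oracle_median(img$pixels, 5L))

  expect_identical(denoise(img, "none")$pixels, img$pixels)
  expect_error(denoise(img, window = 4), "odd")
})

test_that("denoising is idempotent on constants and never expands the range", {
  set.seed(5)
  for (i in 1:5) {
    img <- rand_gray(12, 12)
    out <- denoise(img)
    expect_gte(min(out$pixels), min(img$pixels))
    expect_lte(max(out$pixels), max(img$pixels))
  }
})

test_that("mse follows its definition and is symmetric", {
  a <- gray_image(matrix(0L, 2, 2))
  expect_identical(mse(a, a), 0)
  b <- gray_image(matrix(2L, 2, 2))
  expect_equal(mse(a, b), 4.0)

  x <- gray_image(matrix(c(0L, 20L, 10L, 30L), 2, 2))
  y <- gray_image(matrix(c(1L, 17L, 12L, 34L), 2, 2))
  expect_equal(mse(x, y), (1 + 4 + 9 + 16) / 4)
  expect_equal(mse(x, y), mse(y, x))
  expect_error(mse(a, gray_image(matrix(0L, 3, 3))), "shape")
})

test_that("psnr implements both formulas and decreases with mse", {
  a <- gray_image(matrix(0L, 2, 2))
  expect_identical(psnr(a, a), Inf)
  b <- gray_image(matrix(2L, 2, 2))                  # mse 4
  expect_equal(psnr(a, b, "as_printed"), 20 * log10(255 / 4))
  expect_equal(psnr(a, b, "standard"), 20 * log10(255 / 2))

  c4 <- gray_image(matrix(4L, 2, 2))                 # mse 16
  for (f in c("as_printed", "standard"))
    expect_lt(psnr(a, c4, f), psnr(a, b, f))
})

test_that("quality_report bundles metrics with region areas", {
  a <- gray_image(matrix(0L, 4, 4))
  b <- gray_image(matrix(2L, 4, 4))
  mask <- binary_mask(matrix(c(rep(TRUE, 5), rep(FALSE, 11)), 4, 4))
  q <- quality_report(a, b, mask)
  expect_equal(q$mse, 4.0)
  expect_equal(q$area_image_px, 16L)
  expect_equal(q$area_region_px, 5L)
  expect_identical(quality_report(a, a)$psnr_db, Inf)
})
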