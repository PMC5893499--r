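#' Read a grayscale medical image
#'
#' Reads a single-frame 2D image from PNG, TIFF or DICOM and returns an
#' 8-bit [gray_image]. Color inputs are converted to luminance with the
#' standard weights (0.299, 0.587, 0.114); sources with more than 8 bits
#' per pixel are min-max rescaled to `[0, 255]` (a constant image maps to
#' all-zero), so that downstream quantization and the peak-signal formula
#' use `m = 8` uniformly.
#'
#' @param path Path to the image file.
#' @param dialect One of `"auto"` (by file extension), `"png"`, `"tiff"`,
#'   `"dicom"`.
#' @return A [gray_image] with `bit_depth = 8`.
#' @seealso [save_image_png()]
#' @export
load_image <- function(path, dialect = c("auto", "png", "tiff", "dicom")) {
  dialect <- match.arg(dialect)
  if (!is.character(path) || length(path) != 1L)
    abort_validation("path must be a single file path")
  if (!file.exists(path)) abort_io("file not found: ", path)
  if (dialect == "auto") {
    ext <- tolower(tools::file_ext(path))
    dialect <- switch(ext,
      png = "png", tif = "tiff", tiff = "tiff",
      dcm = "dicom", dicom = "dicom",
      abort_io("cannot infer dialect from extension '", ext, "': ", path))
  }
  switch(dialect,
    png   = load_png(path),
    tiff  = load_tiff(path),
    dicom = load_dicom(path))
}

to_luminance <- function(arr) {
  if (length(dim(arr)) == 2L) return(arr)
  nc <- dim(arr)[3]
  if (nc == 1L) return(arr[, , 1L])
  if (nc == 2L) return(arr[, , 1L])                # gray + alpha
  0.299 * arr[, , 1L] + 0.587 * arr[, , 2L] + 0.114 * arr[, , 3L]
}

load_png <- function(path) {
  arr <- tryCatch(png::readPNG(path),
                  error = function(e) abort_io("failed to read PNG ", path,
                                               ": ", conditionMessage(e)))
  if (length(arr) == 0L) abort_validation("zero-area image: ", path)
  # detect the source depth from per-channel integrality on the 8-bit
  # scale, before any (generally non-integral) luminance combination
  v8 <- arr * 255
  if (max(abs(v8 - round(v8))) < 1e-6) {
    px <- round(to_luminance(round(v8)))           # true 8-bit source
  } else {
    px <- rescale_to_8bit(round(to_luminance(round(arr * 65535))))
  }
  gray_image(px, bit_depth = 8L)
}

load_tiff <- function(path) {
  arr <- tryCatch(tiff::readTIFF(path, as.is = TRUE, info = TRUE),
                  error = function(e) abort_io("failed to read TIFF ", path,
                                               ": ", conditionMessage(e)))
  bits <- attr(arr, "bits.per.sample")
  g <- to_luminance(if (is.array(arr)) arr else as.matrix(arr))
  if (length(g) == 0L) abort_validation("zero-area image: ", path)
  if (is.null(bits)) bits <- if (max(g) > 255) 16L else 8L
  px <- if (bits > 8L) rescale_to_8bit(round(g)) else round(g)
  storage.mode(px) <- "integer"
  gray_image(px, bit_depth = 8L)
}

load_dicom <- function(path) {
  d <- tryCatch(read_dicom_raw(path),
                error = function(e) abort_io("failed to read DICOM ", path,
                                             ": ", conditionMessage(e)))
  if (d$samples_per_pixel != 1L)
    abort_validation("only single-sample (grayscale) DICOM supported")
  if (d$n_frames > 1L)
    abort_validation("multi-frame DICOM not supported (",
                     d$n_frames, " frames): ", path)
  px <- d$pixels
  if (length(px) == 0L) abort_validation("zero-area image: ", path)
  px <- if (d$bits_stored > 8L) rescale_to_8bit(px) else px
  storage.mode(px) <- "integer"
  gray_image(px, bit_depth = 8L)
}

# Minimal single-frame DICOM reader: little-endian explicit or implicit VR,
# uncompressed pixel data only. Sequences with undefined length and
# compressed transfer syntaxes are rejected.
read_dicom_raw <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  sz <- file.size(path)
  preamble <- readBin(con, "raw", 132L)
  if (length(preamble) < 132L || rawToChar(preamble[129:132]) != "DICM")
    stop("missing DICM magic")

  read_u16 <- function() readBin(con, "integer", 1L, size = 2L,
                                 signed = FALSE, endian = "little")
  read_u32 <- function() readBin(con, "integer", 1L, size = 4L,
                                 endian = "little")

  long_vrs <- c("OB", "OW", "OF", "OD", "SQ", "UT", "UN")
  tags <- list()
  explicit <- TRUE              # file meta group is always explicit VR LE
  transfer_syntax <- "1.2.840.10008.1.2.1"
  meta_done <- FALSE

  repeat {
    if (seek(con, where = NA) >= sz) break
    group <- read_u16(); elem <- read_u16()
    if (length(group) == 0L) break
    if (!meta_done && group > 2L) {
      meta_done <- TRUE
      explicit <- transfer_syntax != "1.2.840.10008.1.2"
      if (!transfer_syntax %in%
          c("1.2.840.10008.1.2", "1.2.840.10008.1.2.1"))
        stop("unsupported transfer syntax ", transfer_syntax)
    }
    exp_here <- if (group == 2L) TRUE else explicit
    if (exp_here) {
      vr <- rawToChar(readBin(con, "raw", 2L))
      if (vr %in% long_vrs) {
        readBin(con, "raw", 2L)              # reserved
        len <- read_u32()
      } else len <- read_u16()
    } else {
      vr <- "UN"
      len <- read_u32()
    }
    if (len == -1L) stop("undefined-length element not supported")
    key <- sprintf("%04x,%04x", group, elem)
    payload <- readBin(con, "raw", len)
    tags[[key]] <- list(vr = vr, bytes = payload)
    if (key == "0002,0010")
      transfer_syntax <-
        trimws(rawToChar(payload[payload != as.raw(0)]))
    if (key == "7fe0,0010") break            # pixel data is last we need
  }

  need <- function(key, what) {
    if (is.null(tags[[key]])) stop("missing DICOM tag (", key, ") ", what)
    tags[[key]]
  }
  u16_of <- function(key, default = NULL, what = "") {
    t <- tags[[key]]
    if (is.null(t)) {
      if (is.null(default)) stop("missing DICOM tag (", key, ") ", what)
      return(default)
    }
    readBin(t$bytes, "integer", 1L, size = 2L, signed = FALSE,
            endian = "little")
  }
  rows <- u16_of("0028,0010", what = "Rows")
  cols <- u16_of("0028,0011", what = "Columns")
  bits_alloc <- u16_of("0028,0100", default = 16L)
  bits_stored <- u16_of("0028,0101", default = bits_alloc)
  pixel_rep <- u16_of("0028,0103", default = 0L)
  samples <- u16_of("0028,0002", default = 1L)
  nf_tag <- tags[["0028,0008"]]
  n_frames <- if (is.null(nf_tag)) 1L else
    as.integer(trimws(rawToChar(nf_tag$bytes)))

  pd <- need("7fe0,0010", "PixelData")
  npix <- rows * cols
  if (bits_alloc == 8L) {
    v <- as.integer(pd$bytes[seq_len(npix)])
  } else if (bits_alloc == 16L) {
    v <- readBin(pd$bytes, "integer", npix, size = 2L,
                 signed = pixel_rep == 1L, endian = "little")
  } else stop("unsupported BitsAllocated ", bits_alloc)
  if (any(v < 0)) v <- v - min(v)            # signed data shifted to >= 0
  pixels <- matrix(v, nrow = rows, ncol = cols, byrow = TRUE)
  list(pixels = pixels, bits_stored = bits_stored,
       samples_per_pixel = samples, n_frames = n_frames)
}

#' Write an image or mask as 8-bit PNG
#'
#' @param x A [gray_image] or [binary_mask]. Masks are written as 0/255.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
save_image_png <- function(x, path) {
  if (is_binary_mask(x)) {
    arr <- unclass(x) * 1.0
  } else {
    assert_gray_image(x, "x")
    arr <- x$pixels / (2^x$bit_depth - 1)
  }
  png::writePNG(arr, path)
  invisible(path)
}
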