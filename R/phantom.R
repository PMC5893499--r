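#' Specification of a synthetic brain phantom
#'
#' Describes one synthetic 8-bit grayscale "brain" image: an elliptical
#' brain region filled with a smooth random texture on a dark background,
#' optionally containing a brighter elliptical tumor, degraded by additive
#' Gaussian noise and salt-and-pepper impulses. The phantom stands in for
#' clinical data: it gives every pipeline stage a ground-truth mask and
#' label by construction.
#'
#' @param size `(rows, cols)` image size (default `c(128, 128)`).
#' @param brain_axes Ellipse semi-axes `(a, b)` of the brain region in
#'   pixels, row and column directions (default `c(48, 40)`).
#' @param brain_intensity Mean gray level inside the brain (default 120).
#' @param texture_scale Correlation length of the background texture in
#'   pixels (Gaussian blur SD of a white-noise field, default 3). `Inf`
#'   gives a flat background.
#' @param texture_amp Standard deviation of the texture in gray levels
#'   (default 5, chosen so the default region-growing tolerance can track
#'   intra-region texture variation).
#' @param tumor_present Whether a tumor ellipse is drawn (default TRUE).
#' @param tumor_center Tumor center `(row, col)`; default slightly off the
#'   brain center.
#' @param tumor_axes Tumor ellipse semi-axes in pixels (default `c(12, 9)`).
#' @param tumor_intensity_offset Gray levels added inside the tumor
#'   (default 80).
#' @param noise_sigma SD of additive Gaussian noise (default 5).
#' @param impulse_fraction Fraction of pixels replaced by 0/255 impulses,
#'   in `[0, 0.1]` (default 0.02).
#' @param seed RNG seed; the phantom is deterministic given the spec.
#' @return A `phantom_spec` list.
#' @export
phantom_spec <- function(size = c(128L, 128L),
                         brain_axes = c(48, 40),
                         brain_intensity = 120,
                         texture_scale = 3,
                         texture_amp = 5,
                         tumor_present = TRUE,
                         tumor_center = NULL,
                         tumor_axes = c(12, 9),
                         tumor_intensity_offset = 80,
                         noise_sigma = 5,
                         impulse_fraction = 0.02,
                         seed = 1L) {
  if (length(size) != 2L || any(size < 8))
    abort_validation("size must be (rows, cols), each >= 8")
  if (any(brain_axes <= 0) || any(tumor_axes <= 0))
    abort_validation("ellipse semi-axes must be positive")
  if (impulse_fraction < 0 || impulse_fraction > 0.1)
    abort_validation("impulse_fraction must be in [0, 0.1]")
  if (noise_sigma < 0) abort_validation("noise_sigma must be >= 0")
  if (is.null(tumor_center))
    tumor_center <- round(size / 2) + c(8, 6)
  structure(list(size = as.integer(size), brain_axes = brain_axes,
                 brain_intensity = brain_intensity,
                 texture_scale = texture_scale, texture_amp = texture_amp,
                 tumor_present = isTRUE(tumor_present),
                 tumor_center = tumor_center, tumor_axes = tumor_axes,
                 tumor_intensity_offset = tumor_intensity_offset,
                 noise_sigma = noise_sigma,
                 impulse_fraction = impulse_fraction,
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

ellipse_mask <- function(size, center, axes) {
  rr <- matrix(seq_len(size[1L]), size[1L], size[2L])
  cc <- matrix(seq_len(size[2L]), size[1L], size[2L], byrow = TRUE)
  ((rr - center[1L]) / axes[1L])^2 + ((cc - center[2L]) / axes[2L])^2 <= 1
}

# separable Gaussian blur with replicate padding
gaussian_blur <- function(m, sd) {
  if (sd <= 0) return(m)
  rad <- max(1L, ceiling(3 * sd))
  k <- exp(-(seq(-rad, rad))^2 / (2 * sd^2))
  k <- k / sum(k)
  blur_dim1 <- function(x) {
    n <- nrow(x)
    idx <- pmin(pmax(seq_len(n + 2L * rad) - rad, 1L), n)
    e <- x[idx, , drop = FALSE]
    out <- matrix(0, n, ncol(x))
    for (j in seq_along(k))
      out <- out + k[j] * e[(j - 1L) + seq_len(n), , drop = FALSE]
    out
  }
  t(blur_dim1(t(blur_dim1(m))))
}

#' Generate a synthetic brain phantom
#'
#' Renders the phantom described by a [phantom_spec()]: smooth texture at
#' `brain_intensity` inside the brain ellipse, 0 outside; the tumor
#' ellipse (when present) adds `tumor_intensity_offset`; Gaussian noise
#' and then salt-and-pepper impulses are applied; intensities are clipped
#' to `[0, 255]`. The returned mask is the exact tumor ellipse (all-false
#' for a normal phantom) and the label depends only on `tumor_present`.
#' Output is deterministic given the spec (including its seed).
#'
#' @param spec A [phantom_spec()].
#' @return List with `image` ([gray_image]), `mask` ([binary_mask]) and
#'   `label` (`"normal"` or `"abnormal"`).
#' @export
generate_phantom <- function(spec) {
  if (!inherits(spec, "phantom_spec"))
    abort_validation("spec must be a phantom_spec")
  size <- spec$size
  brain_center <- (size + 1) / 2
  brain <- ellipse_mask(size, brain_center, spec$brain_axes)
  tumor <- if (spec$tumor_present)
    ellipse_mask(size, spec$tumor_center, spec$tumor_axes)
  else matrix(FALSE, size[1L], size[2L])
  if (spec$tumor_present && any(tumor & !brain))
    abort_validation("tumor ellipse extends outside the brain ellipse")

  img <- with_seed(spec$seed, {
    base <- matrix(0, size[1L], size[2L])
    if (is.finite(spec$texture_scale) && spec$texture_amp > 0) {
      tex <- matrix(stats::rnorm(prod(size)), size[1L], size[2L])
      tex <- gaussian_blur(tex, spec$texture_scale)
      tex <- (tex - mean(tex)) / stats::sd(tex) * spec$texture_amp
    } else {
      tex <- base
    }
    out <- base
    out[brain] <- spec$brain_intensity + tex[brain]
    out[tumor] <- out[tumor] + spec$tumor_intensity_offset
    if (spec$noise_sigma > 0)
      out <- out + stats::rnorm(prod(size), sd = spec$noise_sigma)
    if (spec$impulse_fraction > 0) {
      n_imp <- round(spec$impulse_fraction * prod(size))
      if (n_imp > 0) {
        at <- sample.int(prod(size), n_imp)
        out[at] <- sample(c(0, 255), n_imp, replace = TRUE)
      }
    }
    pmin(pmax(round(out), 0), 255)
  })
  list(image = gray_image(img, 8L),
       mask = binary_mask(tumor),
       label = if (spec$tumor_present) "abnormal" else "normal")
}

#' Generate a labeled phantom dataset
#'
#' Draws `n_normal` normal and `n_abnormal` abnormal phantoms (in that
#' order) from `base_spec`, jittering tumor position, semi-axes and
#' intensity offset within the given ranges using a seeded RNG, so the
#' whole dataset is reproducible.
#'
#' @param n_normal,n_abnormal Item counts (>= 0).
#' @param base_spec Template [phantom_spec()].
#' @param jitter List with `center` (max absolute shift of the tumor
#'   center, px), `axes` (range of each semi-axis, px) and `offset`
#'   (range of the tumor intensity offset, gray levels).
#' @param seed Master seed for the dataset.
#' @return List of phantom records (`image`, `mask`, `label`), length
#'   `n_normal + n_abnormal`.
#' @export
generate_dataset <- function(n_normal, n_abnormal,
                             base_spec = phantom_spec(),
                             jitter = list(center = 6, axes = c(8, 14),
                                           offset = c(60, 100)),
                             seed = 1L) {
  if (!is_count(n_normal) || !is_count(n_abnormal))
    abort_validation("counts must be non-negative integers")
  n <- n_normal + n_abnormal
  if (n == 0L) return(list())
  if (jitter$axes[1L] <= 0 || diff(jitter$axes) < 0 ||
      diff(jitter$offset) < 0 || jitter$center < 0)
    abort_validation("invalid jitter ranges")
  params <- with_seed(seed, {
    lapply(seq_len(n), function(i) list(
      seed = sample.int(.Machine$integer.max - 1L, 1L),
      dc = round(stats::runif(2, -jitter$center, jitter$center)),
      axes = stats::runif(2, jitter$axes[1L], jitter$axes[2L]),
      offset = stats::runif(1, jitter$offset[1L], jitter$offset[2L])))
  })
  out <- vector("list", n)
  for (i in seq_len(n)) {
    p <- params[[i]]
    sp <- base_spec
    sp$seed <- p$seed
    sp$tumor_present <- i > n_normal
    sp$tumor_center <- base_spec$tumor_center + p$dc
    sp$tumor_axes <- p$axes
    sp$tumor_intensity_offset <- p$offset
    out[[i]] <- generate_phantom(sp)
  }
  out
}

#' Write a phantom dataset to disk
#'
#' Writes `img_####.png`, `mask_####.png` and a `labels.csv`
#' (`filename,label`) into `dir`, the on-disk layout consumed by
#' [run_experiment()].
#'
#' @param dataset Output of [generate_dataset()].
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- sprintf("img_%04d.png", seq_along(dataset))
  for (i in seq_along(dataset)) {
    save_image_png(dataset[[i]]$image, file.path(dir, files[i]))
    save_image_png(dataset[[i]]$mask,
                   file.path(dir, sub("^img_", "mask_", files[i])))
  }
  labels <- data.frame(
    filename = files,
    label = vapply(dataset, `[[`, character(1), "label"))
  utils::write.csv(labels, file.path(dir, "labels.csv"),
                   row.names = FALSE, quote = FALSE)
  invisible(dir)
}
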