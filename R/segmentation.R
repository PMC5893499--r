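#' Seeded region growing
#'
#' Grows a region outward from one or more seed pixels. Pixels are examined
#' in breadth-first (FIFO) order; an unvisited neighbor joins the region iff
#' the absolute difference between its intensity and the current region mean
#' is at most `delta`. Neighbors are pushed in a fixed order — up, left,
#' right, down, then the four diagonals for 8-connectivity — which makes the
#' running-mean variant deterministic. All seeds are members of the region
#' unconditionally.
#'
#' With `mean_mode = "running"` the region mean is updated after every
#' accepted pixel; with `"fixed"` it stays at the mean of the seed
#' intensities. Pixels are examined at most once: a pixel rejected under the
#' mean current at examination time is not revisited.
#'
#' @param img A [gray_image].
#' @param seeds Integer matrix or two-column data frame of seed `(row, col)`
#'   coordinates (1-based), or a length-2 vector for a single seed.
#' @param delta Non-negative intensity tolerance (default 10 on the 8-bit
#'   scale); `Inf` grows over the whole connected image.
#' @param connectivity 4 (default) or 8.
#' @param mean_mode `"running"` (default) or `"fixed"`.
#' @return A [binary_mask], a single connected component containing all seeds.
#' @examples
#' img <- gray_image(cbind(matrix(10L, 3, 2), matrix(50L, 3, 1)))
#' grow_region(img, c(1, 1), delta = 5)
#' @export
grow_region <- function(img, seeds, delta = 10,
                        connectivity = 4L,
                        mean_mode = c("running", "fixed")) {
  assert_gray_image(img)
  mean_mode <- match.arg(mean_mode)
  if (!connectivity %in% c(4L, 8L))
    abort_validation("connectivity must be 4 or 8")
  if (!is.numeric(delta) || length(delta) != 1L || is.na(delta) || delta < 0)
    abort_validation("delta must be a non-negative number")
  seeds <- as_seed_matrix(seeds)
  r <- nrow(img$pixels); cl <- ncol(img$pixels)
  if (any(seeds[, 1L] < 1L | seeds[, 1L] > r |
          seeds[, 2L] < 1L | seeds[, 2L] > cl))
    abort_validation("seed outside image bounds")

  px <- img$pixels
  visited <- matrix(FALSE, r, cl)
  member <- matrix(FALSE, r, cl)

  dr4 <- c(-1L, 0L, 0L, 1L); dc4 <- c(0L, -1L, 1L, 0L)
  if (connectivity == 8L) {
    dr <- c(dr4, -1L, -1L, 1L, 1L); dc <- c(dc4, -1L, 1L, -1L, 1L)
  } else { dr <- dr4; dc <- dc4 }

  # FIFO queue of linear indices
  cap <- max(64L, 2L * nrow(seeds))
  queue <- integer(cap); head <- 1L; tail <- 0L
  push <- function(i) {
    if (tail == length(queue)) queue <<- c(queue, integer(length(queue)))
    tail <<- tail + 1L; queue[tail] <<- i
  }

  seed_idx <- unique((seeds[, 2L] - 1L) * r + seeds[, 1L])
  reg_sum <- sum(as.numeric(px[seed_idx]))
  reg_n <- length(seed_idx)
  for (i in seed_idx) { visited[i] <- TRUE; member[i] <- TRUE; push(i) }
  fixed_mean <- reg_sum / reg_n

  while (head <= tail) {
    i <- queue[head]; head <- head + 1L
    ri <- ((i - 1L) %% r) + 1L
    ci <- ((i - 1L) %/% r) + 1L
    for (k in seq_along(dr)) {
      nr <- ri + dr[k]; nc <- ci + dc[k]
      if (nr < 1L || nr > r || nc < 1L || nc > cl) next
      j <- (nc - 1L) * r + nr
      if (visited[j]) next
      visited[j] <- TRUE
      m <- if (mean_mode == "running") reg_sum / reg_n else fixed_mean
      if (abs(px[j] - m) <= delta) {
        member[j] <- TRUE
        reg_sum <- reg_sum + px[j]; reg_n <- reg_n + 1L
        push(j)
      }
    }
  }
  binary_mask(member)
}

as_seed_matrix <- function(seeds) {
  if (is.data.frame(seeds)) seeds <- as.matrix(seeds)
  if (is.numeric(seeds) && is.null(dim(seeds))) {
    if (length(seeds) != 2L)
      abort_validation("a single seed must be a (row, col) pair")
    seeds <- matrix(seeds, 1L, 2L)
  }
  if (!is.matrix(seeds) || ncol(seeds) != 2L || nrow(seeds) < 1L)
    abort_validation("seeds must be a non-empty two-column (row, col) matrix")
  if (any(seeds != round(seeds))) abort_validation("seeds must be integer")
  storage.mode(seeds) <- "integer"
  seeds
}

#' Automatic seed selection
#'
#' Picks the centroid of the brightest fraction of pixels, for pipelines
#' without user-supplied seeds. If the centroid falls outside the bright
#' set (possible for disconnected bright regions) the brightest pixel
#' nearest the centroid is used instead.
#'
#' @param img A [gray_image], typically already denoised.
#' @param frac Fraction of brightest pixels considered (default 0.01).
#' @return A 1x2 integer matrix of the seed `(row, col)`.
#' @export
auto_seed <- function(img, frac = 0.01) {
  assert_gray_image(img)
  if (!is_scalar_number(frac) || frac <= 0 || frac > 1)
    abort_validation("frac must be in (0, 1]")
  px <- img$pixels
  n <- length(px)
  k <- max(1L, floor(frac * n))
  thr <- sort(as.vector(px), decreasing = TRUE)[k]
  idx <- which(px >= thr)
  rr <- ((idx - 1L) %% nrow(px)) + 1L
  cc <- ((idx - 1L) %/% nrow(px)) + 1L
  cr <- round(mean(rr)); cc0 <- round(mean(cc))
  if (!any(rr == cr & cc == cc0)) {
    d2 <- (rr - cr)^2 + (cc - cc0)^2
    j <- which.min(d2)
    cr <- rr[j]; cc0 <- cc[j]
  }
  matrix(c(cr, cc0), 1L, 2L)
}

#' Structuring element for binary morphology
#'
#' @param shape `"square"`, `"cross"`, or `"custom"` (supply `footprint`).
#' @param size Side length for the built-in shapes (odd, default 3).
#' @param footprint Logical matrix for `shape = "custom"`.
#' @param origin `(row, col)` of the origin within the footprint; defaults
#'   to the center. The origin cell must be part of the footprint.
#' @return A `structuring_element` with fields `footprint` and `origin`.
#' @export
structuring_element <- function(shape = c("square", "cross", "custom"),
                                size = 3L, footprint = NULL, origin = NULL) {
  shape <- match.arg(shape)
  if (shape != "custom") {
    if (!is_count(size, 1L) || size %% 2L == 0L)
      abort_validation("size must be an odd positive integer")
    footprint <- matrix(TRUE, size, size)
    if (shape == "cross") {
      c0 <- (size + 1L) %/% 2L
      footprint[,] <- FALSE
      footprint[c0, ] <- TRUE
      footprint[, c0] <- TRUE
    }
  }
  if (!is.matrix(footprint) || !is.logical(footprint) || !any(footprint))
    abort_validation("footprint must be a non-empty logical matrix")
  if (is.null(origin))
    origin <- c((nrow(footprint) + 1L) %/% 2L, (ncol(footprint) + 1L) %/% 2L)
  origin <- as.integer(origin)
  if (length(origin) != 2L ||
      origin[1L] < 1L || origin[1L] > nrow(footprint) ||
      origin[2L] < 1L || origin[2L] > ncol(footprint) ||
      !footprint[origin[1L], origin[2L]])
    abort_validation("origin must index a true footprint cell")
  structure(list(footprint = footprint, origin = origin),
            class = "structuring_element")
}

se_offsets <- function(se) {
  w <- which(se$footprint, arr.ind = TRUE)
  cbind(w[, 1L] - se$origin[1L], w[, 2L] - se$origin[2L])
}

# translate mask by (dr, dc), filling with FALSE
shift_mask <- function(m, dr, dc) {
  r <- nrow(m); cl <- ncol(m)
  out <- matrix(FALSE, r, cl)
  rs <- max(1L, 1L + dr):min(r, r + dr)
  cs <- max(1L, 1L + dc):min(cl, cl + dc)
  if (dr >= r || dr <= -r || dc >= cl || dc <= -cl) return(out)
  out[rs, cs] <- m[rs - dr, cs - dc, drop = FALSE]
  out
}

#' Binary dilation and erosion
#'
#' `dilate()` sets a cell when the reflected structuring element placed
#' there overlaps any foreground cell; `erode()` keeps a cell only when the
#' whole footprint placed there lies on foreground. Pixels outside the
#' image are treated as background in both.
#'
#' @param mask A [binary_mask].
#' @param se A [structuring_element] (default 3x3 square).
#' @return A [binary_mask] of the same shape.
#' @export
dilate <- function(mask, se = structuring_element()) {
  mask <- as_mask(unclass(mask))
  off <- se_offsets(se)
  out <- matrix(FALSE, nrow(mask), ncol(mask))
  for (k in seq_len(nrow(off)))
    out <- out | shift_mask(unclass(mask), off[k, 1L], off[k, 2L])
  binary_mask(out)
}

#' @rdname dilate
#' @export
erode <- function(mask, se = structuring_element()) {
  mask <- as_mask(unclass(mask))
  off <- se_offsets(se)
  out <- matrix(TRUE, nrow(mask), ncol(mask))
  for (k in seq_len(nrow(off)))
    out <- out & shift_mask(unclass(mask), -off[k, 1L], -off[k, 2L])
  binary_mask(out)
}

#' Morphological cleanup of a segmentation mask
#'
#' Applies an opening (erosion then dilation with the same structuring
#' element), removes 8-connected components smaller than
#' `min_component_px`, and returns only the largest surviving component
#' (ties broken by scan order, column-major). An empty result signals that
#' no tumor-like region survived.
#'
#' @inheritParams dilate
#' @param min_component_px Minimum component size in pixels (default 25).
#' @return A [binary_mask] with zero or one connected component.
#' @export
clean_mask <- function(mask, se = structuring_element(),
                       min_component_px = 25L) {
  if (!is_count(min_component_px))
    abort_validation("min_component_px must be a non-negative integer")
  opened <- dilate(erode(mask, se), se)
  lab <- label_components(opened, connectivity = 8L)
  if (lab$n == 0L) return(binary_mask(matrix(FALSE, nrow(mask), ncol(mask))))
  sizes <- tabulate(lab$labels[lab$labels > 0L], nbins = lab$n)
  keep <- which(sizes >= min_component_px)
  if (length(keep) == 0L)
    return(binary_mask(matrix(FALSE, nrow(mask), ncol(mask))))
  best <- keep[which.max(sizes[keep])]
  binary_mask(matrix(lab$labels == best, nrow(mask), ncol(mask)))
}

# BFS connected-component labeling; labels assigned in column-major scan
# order so largest-component ties resolve stably
label_components <- function(mask, connectivity = 8L) {
  m <- unclass(mask)
  r <- nrow(m); cl <- ncol(m)
  labels <- matrix(0L, r, cl)
  dr <- c(-1L, 0L, 0L, 1L); dc <- c(0L, -1L, 1L, 0L)
  if (connectivity == 8L) {
    dr <- c(dr, -1L, -1L, 1L, 1L); dc <- c(dc, -1L, 1L, -1L, 1L)
  }
  n <- 0L
  queue <- integer(256L)
  for (start in which(m)) {
    if (labels[start] > 0L) next
    n <- n + 1L
    labels[start] <- n
    head <- 1L; tail <- 1L; queue[1L] <- start
    while (head <= tail) {
      i <- queue[head]; head <- head + 1L
      ri <- ((i - 1L) %% r) + 1L
      ci <- ((i - 1L) %/% r) + 1L
      for (k in seq_along(dr)) {
        nr <- ri + dr[k]; nc <- ci + dc[k]
        if (nr < 1L || nr > r || nc < 1L || nc > cl) next
        j <- (nc - 1L) * r + nr
        if (m[j] && labels[j] == 0L) {
          labels[j] <- n
          if (tail == length(queue)) queue <- c(queue, integer(length(queue)))
          tail <- tail + 1L; queue[tail] <- j
        }
      }
    }
  }
  list(labels = labels, n = n)
}

#' Region area in pixels
#'
#' @param mask A [binary_mask].
#' @return Integer count of foreground cells.
#' @export
region_area <- function(mask) {
  if (!is_binary_mask(mask) && !(is.matrix(mask) && is.logical(mask)))
    abort_validation("mask must be a binary_mask or logical matrix")
  as.integer(sum(mask))
}
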