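#' Orthonormal wavelet filter pairs
#'
#' Returns the scaling (low-pass) and wavelet (high-pass) analysis filters
#' for the supported orthonormal families. The high-pass filter is the
#' quadrature mirror of the low-pass: `hi[k] = (-1)^(k-1) * lo[f-k+1]`.
#' For `"haar"` this yields detail coefficients `(x1 - x2)/sqrt(2)` on each
#' sample pair.
#'
#' @param name `"haar"`, `"db2"` or `"db4"` (Daubechies, 4 and 8 taps).
#' @return List with `lo`, `hi` and tap count `f`.
#' @export
wavelet_filters <- function(name = c("haar", "db2", "db4")) {
  name <- match.arg(name)
  lo <- switch(name,
    haar = c(1, 1) / sqrt(2),
    db2 = {
      s3 <- sqrt(3)
      c(1 + s3, 3 + s3, 3 - s3, 1 - s3) / (4 * sqrt(2))
    },
    db4 = c(0.230377813308855230, 0.714846570552541500,
            0.630880767929590400, -0.027983769416983849,
            -0.187034811718881140, 0.030841381835986965,
            0.032883011666982945, -0.010597401784997278))
  f <- length(lo)
  hi <- rev(lo) * (-1)^(seq_len(f) - 1L)
  list(lo = lo, hi = hi, f = f)
}

# map any integer index onto 1..n by half-point symmetric reflection
sym_index <- function(i, n) {
  j <- ((i - 1L) %% (2L * n)) + 1L
  ifelse(j <= n, j, 2L * n + 1L - j)
}

# one analysis step along dim 1 (down the columns); returns L and H halves
dwt_step_dim1 <- function(X, flt, boundary) {
  n <- nrow(X); f <- flt$f; p <- f - 1L
  if (boundary == "symmetric") {
    ext_idx <- sym_index(seq_len(n + 2L * p) - p, n)
    L_out <- (n + f - 1L) %/% 2L
  } else {                               # periodization; odd n pads last row
    n_eff <- if (n %% 2L == 1L) n + 1L else n
    per <- function(i) ((i - 1L) %% n_eff) + 1L
    base <- c(seq_len(n), if (n_eff > n) n)   # padded signal indices
    ext_idx <- base[per(seq_len(n_eff + 2L * p) - p)]
    L_out <- n_eff %/% 2L
  }
  E <- X[ext_idx, , drop = FALSE]
  A <- matrix(0, L_out, ncol(X))
  D <- matrix(0, L_out, ncol(X))
  ks <- 2L * seq_len(L_out)
  for (j in seq_len(f)) {
    rows <- E[ks + j - 1L, , drop = FALSE]
    A <- A + flt$lo[j] * rows
    D <- D + flt$hi[j] * rows
  }
  list(A = A, D = D)
}

# inverse of dwt_step_dim1; reconstructs to n_orig rows
idwt_step_dim1 <- function(A, D, flt, boundary, n_orig) {
  f <- flt$f; L <- nrow(A); nc <- ncol(A)
  if (boundary == "symmetric") {
    U_A <- matrix(0, 2L * L, nc); U_A[seq(1L, 2L * L, 2L), ] <- A
    U_D <- matrix(0, 2L * L, nc); U_D[seq(1L, 2L * L, 2L), ] <- D
    Y <- matrix(0, 2L * L + f - 1L, nc)
    for (j in seq_len(f)) {
      rows <- j:(j + 2L * L - 1L)
      Y[rows, ] <- Y[rows, ] + flt$lo[j] * U_A + flt$hi[j] * U_D
    }
    Y <- Y[(f - 1L):(2L * L), , drop = FALSE]
    Y[seq_len(n_orig), , drop = FALSE]
  } else {
    n_eff <- 2L * L
    X <- matrix(0, n_eff, nc)
    for (j in seq_len(f)) {
      idx <- ((2L * seq_len(L) + j - f - 1L) %% n_eff) + 1L
      X[idx, ] <- X[idx, ] + flt$lo[j] * A + flt$hi[j] * D
    }
    X[seq_len(n_orig), , drop = FALSE]
  }
}

subband_dims <- function(n, f, boundary) {
  if (boundary == "symmetric") (n + f - 1L) %/% 2L
  else (n + n %% 2L) %/% 2L
}

#' Multilevel 2D discrete wavelet decomposition
#'
#' Separable analysis filter bank with dyadic downsampling. Level 1 is
#' computed from the input image; each further level decomposes the
#' previous level's LL (approximation) subband. Subbands are named `"AB"`
#' where the first letter is the filter applied along the row axis
#' (vertical direction) and the second along the column axis, so `LL` is
#' the approximation, `HL` carries detail that is high-frequency
#' vertically, `LH` horizontally, and `HH` diagonally.
#'
#' Boundary handling: `"symmetric"` (default) uses half-point symmetric
#' extension and subband sizes `floor((n + f - 1)/2)`; `"periodic"` uses
#' periodized circular filtering with subband sizes `ceil(n/2)`. Both
#' reconstruct perfectly through [idwt2()]; only the periodic mode keeps
#' the transform orthonormal (and hence exactly energy-preserving) at the
#' borders.
#'
#' @param img A [gray_image] or numeric matrix.
#' @param wavelet Filter family, see [wavelet_filters()]. Default `"haar"`.
#' @param levels Decomposition depth (default 4).
#' @param boundary `"symmetric"` (default) or `"periodic"`.
#' @return A `wavelet_decomposition`: list with `levels` (each a list of
#'   `LL`, `LH`, `HL`, `HH` coefficient matrices), `wavelet`, `boundary`,
#'   and the per-level input dimensions used for reconstruction.
#' @examples
#' dec <- dwt2(gray_image(matrix(sample(0:255, 64 * 64, TRUE), 64, 64)),
#'             levels = 3)
#' dec
#' @export
dwt2 <- function(img, wavelet = "haar", levels = 4L,
                 boundary = c("symmetric", "periodic")) {
  boundary <- match.arg(boundary)
  X <- if (is_gray_image(img)) img$pixels else img
  if (!is.matrix(X) || !is.numeric(X))
    abort_validation("img must be a gray_image or numeric matrix")
  if (!is_count(levels, min = 1L))
    abort_validation("levels must be a positive integer")
  flt <- wavelet_filters(wavelet)

  # feasibility: every level's input must be at least 2x2
  r <- nrow(X); cl <- ncol(X); feasible <- 0L
  rr <- r; cc <- cl
  for (k in seq_len(levels)) {
    if (rr < 2L || cc < 2L) break
    feasible <- k
    rr <- subband_dims(rr, flt$f, boundary)
    cc <- subband_dims(cc, flt$f, boundary)
  }
  if (feasible < levels)
    abort_validation("image ", r, "x", cl, " supports at most ", feasible,
                     " level(s) of '", wavelet, "' decomposition, not ",
                     levels)

  X <- matrix(as.numeric(X), r, cl)
  lev <- vector("list", levels)
  in_dims <- vector("list", levels)
  for (k in seq_len(levels)) {
    in_dims[[k]] <- dim(X)
    s1 <- dwt_step_dim1(X, flt, boundary)              # vertical
    a <- dwt_step_dim1(t(s1$A), flt, boundary)         # horizontal on L
    d <- dwt_step_dim1(t(s1$D), flt, boundary)         # horizontal on H
    lev[[k]] <- list(LL = t(a$A), LH = t(a$D),
                     HL = t(d$A), HH = t(d$D))
    X <- lev[[k]]$LL
  }
  structure(list(levels = lev, wavelet = wavelet, boundary = boundary,
                 input_dims = in_dims),
            class = "wavelet_decomposition")
}

#' @export
print.wavelet_decomposition <- function(x, ...) {
  cat(sprintf("<wavelet_decomposition> %s, %s boundary, %d level(s)\n",
              x$wavelet, x$boundary, length(x$levels)))
  for (k in seq_along(x$levels)) {
    d <- dim(x$levels[[k]]$LL)
    cat(sprintf("  level %d: subbands %d x %d\n", k, d[1], d[2]))
  }
  invisible(x)
}

#' Inverse multilevel 2D wavelet transform
#'
#' Reconstructs the original matrix from a [dwt2()] decomposition. The
#' round trip `idwt2(dwt2(x))` recovers `x` to floating-point precision
#' (perfect reconstruction) in either boundary mode.
#'
#' @param dec A `wavelet_decomposition`.
#' @return Numeric matrix of the original input dimensions.
#' @export
idwt2 <- function(dec) {
  if (!inherits(dec, "wavelet_decomposition"))
    abort_validation("dec must be a wavelet_decomposition")
  flt <- wavelet_filters(dec$wavelet)
  L <- length(dec$levels)
  A <- dec$levels[[L]]$LL
  for (k in rev(seq_len(L))) {
    sb <- dec$levels[[k]]
    nd <- dec$input_dims[[k]]
    # invert horizontal step on both halves, then the vertical step
    low <- t(idwt_step_dim1(t(A), t(sb$LH), flt, dec$boundary, nd[2L]))
    high <- t(idwt_step_dim1(t(sb$HL), t(sb$HH), flt, dec$boundary, nd[2L]))
    A <- idwt_step_dim1(low, high, flt, dec$boundary, nd[1L])
  }
  A
}

#' Select wavelet subbands for texture analysis
#'
#' Projects a decomposition onto the requested `(level, band)`
#' combinations, in deterministic order: levels ascending, `LL` before
#' `HL` (and generally the order `LL`, `LH`, `HL`, `HH` within a level).
#'
#' @param dec A `wavelet_decomposition`.
#' @param levels Integer vector of levels to take (default: all).
#' @param bands Character vector from `c("LL", "LH", "HL", "HH")`;
#'   default `c("LL", "HL")`, the bands used for texture features.
#' @return A list of records `list(level, band, coefficients)`, named
#'   `"L<level>.<band>"`.
#' @export
select_subbands <- function(dec, levels = seq_along(dec$levels),
                            bands = c("LL", "HL")) {
  if (!inherits(dec, "wavelet_decomposition"))
    abort_validation("dec must be a wavelet_decomposition")
  if (length(levels) == 0L || any(!levels %in% seq_along(dec$levels)))
    abort_validation("requested level(s) ",
                     paste(setdiff(levels, seq_along(dec$levels)),
                           collapse = ", "),
                     " not present (decomposition has ",
                     length(dec$levels), ")")
  band_order <- c("LL", "LH", "HL", "HH")
  if (any(!bands %in% band_order))
    abort_validation("bands must be among LL, LH, HL, HH")
  bands <- band_order[band_order %in% bands]
  out <- list()
  for (k in sort(unique(as.integer(levels)))) {
    for (b in bands) {
      out[[sprintf("L%d.%s", k, b)]] <-
        list(level = k, band = b, coefficients = dec$levels[[k]][[b]])
    }
  }
  out
}
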