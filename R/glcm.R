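#' Uniform quantization to G gray levels
#'
#' Bins the value range `[min, max]` of a real array into `G` equal-width
#' bins labeled `0 .. G-1`. A constant array maps to all-zero. Used to
#' discretize real-valued wavelet coefficients before co-occurrence
#' counting.
#'
#' @param arr Numeric matrix.
#' @param G Number of gray levels (>= 2, default 8).
#' @return Integer matrix with values in `[0, G-1]`.
#' @export
quantize <- function(arr, G = 8L) {
  if (!is.matrix(arr) || !is.numeric(arr))
    abort_validation("arr must be a numeric matrix")
  if (!is_count(G, min = 2L)) abort_validation("G must be an integer >= 2")
  lo <- min(arr); hi <- max(arr)
  if (hi == lo) {
    q <- matrix(0L, nrow(arr), ncol(arr))
  } else {
    q <- pmin(floor(G * (arr - lo) / (hi - lo)), G - 1L)
    q <- matrix(as.integer(q), nrow(arr), ncol(arr))
  }
  q
}

glcm_offset <- function(angle, S) {
  switch(as.character(angle),
    "0"   = c(0L, S),
    "45"  = c(-S, S),
    "90"  = c(-S, 0L),
    "135" = c(-S, -S),
    abort_validation("angle must be one of 0, 45, 90, 135"))
}

#' Gray-level co-occurrence matrix
#'
#' Counts how often gray level `p` occurs at a fixed displacement from
#' gray level `q` and normalizes the counts to a probability matrix
#' summing to 1. The displacement is given by a distance `S` and an angle:
#' 0 degrees is horizontal `(0, +S)`, 45 the positive diagonal `(-S, +S)`,
#' 90 vertical `(-S, 0)` and 135 the negative diagonal `(-S, -S)`, in
#' `(row, col)` convention. With `symmetric = TRUE` (the Haralick
#' convention, default) the reverse displacement is counted too, making
#' the matrix symmetric.
#'
#' @param q Integer matrix of quantized gray levels in `[0, G-1]`.
#' @param S Positive integer pixel distance (default 1).
#' @param angle One of 0, 45, 90, 135 (degrees).
#' @param symmetric Count ordered pairs in both directions (default TRUE).
#' @param n_levels Number of gray levels `G`; defaults to `max(q) + 1`.
#' @return A `glcm` object: normalized matrix `mat` (G x G), raw
#'   `counts`, and the parameters.
#' @examples
#' q <- rbind(c(0, 0, 1, 1), c(0, 0, 1, 1), c(0, 2, 2, 2), c(2, 2, 3, 3))
#' glcm(q, S = 1, angle = 0)
#' @export
glcm <- function(q, S = 1L, angle = 0, symmetric = TRUE, n_levels = NULL) {
  if (!is.matrix(q) || !is.numeric(q) || any(q != round(q)) || any(q < 0))
    abort_validation("q must be a matrix of non-negative integers")
  if (!is_count(S, min = 1L)) abort_validation("S must be a positive integer")
  G <- if (is.null(n_levels)) as.integer(max(q) + 1L) else as.integer(n_levels)
  if (any(q > G - 1L)) abort_validation("q has values outside [0, G-1]")
  off <- glcm_offset(angle, as.integer(S))
  r <- nrow(q); cl <- ncol(q)
  rs <- seq_len(r); cs <- seq_len(cl)
  ref_r <- rs[rs >= 1L - off[1L] & rs <= r - off[1L]]
  ref_c <- cs[cs >= 1L - off[2L] & cs <= cl - off[2L]]
  if (length(ref_r) == 0L || length(ref_c) == 0L)
    abort_validation("image too small for distance ", S, " at angle ", angle)
  p_ref <- q[ref_r, ref_c, drop = FALSE]
  p_nbr <- q[ref_r + off[1L], ref_c + off[2L], drop = FALSE]
  idx <- as.vector(p_ref) * G + as.vector(p_nbr) + 1L
  counts <- tabulate(idx, nbins = G * G)
  if (symmetric) {
    idx_rev <- as.vector(p_nbr) * G + as.vector(p_ref) + 1L
    counts <- counts + tabulate(idx_rev, nbins = G * G)
  }
  counts <- matrix(counts, G, G, byrow = TRUE)   # row = reference level p
  total <- sum(counts)
  structure(list(mat = counts / total, counts = counts, n_levels = G,
                 distance = as.integer(S), angle = angle,
                 symmetric = symmetric),
            class = "glcm")
}

#' @export
print.glcm <- function(x, ...) {
  cat(sprintf("<glcm> %d levels, distance %d, angle %d%s, %d pairs\n",
              x$n_levels, x$distance, x$angle,
              if (x$symmetric) " (symmetric)" else "", sum(x$counts)))
  invisible(x)
}

assert_glcm <- function(M) {
  if (!inherits(M, "glcm")) abort_validation("M must be a glcm object")
  invisible(M)
}

#' Haralick texture features of a co-occurrence matrix
#'
#' Five scalar statistics of a normalized GLCM `f(p, q)` with levels
#' indexed `0 .. G-1`:
#' * contrast: `sum (p - q)^2 f(p, q)`
#' * energy: `sqrt(sum f(p, q)^2)` (root included)
#' * correlation: `(sum p q f(p, q) - mu_p mu_q) / (sigma_p sigma_q)`,
#'   with moments from the row and column marginals; undefined (returned
#'   as `NA`) when either marginal variance is zero
#' * homogeneity: `sum f(p, q) / (1 + (p - q)^2)`
#' * entropy: `-sum f log2 f`, with `0 log 0 := 0` (bits)
#'
#' @param M A [glcm()] object.
#' @return A single numeric value.
#' @name glcm-features
NULL

#' @rdname glcm-features
#' @export
glcm_contrast <- function(M) {
  assert_glcm(M)
  G <- M$n_levels
  p <- matrix(0:(G - 1L), G, G)
  q <- t(p)
  sum((p - q)^2 * M$mat)
}

#' @rdname glcm-features
#' @export
glcm_energy <- function(M) {
  assert_glcm(M)
  sqrt(sum(M$mat^2))
}

#' @rdname glcm-features
#' @export
glcm_correlation <- function(M) {
  assert_glcm(M)
  G <- M$n_levels
  lv <- 0:(G - 1L)
  pm <- rowSums(M$mat)           # marginal of reference level p
  qm <- colSums(M$mat)
  mu_p <- sum(lv * pm); mu_q <- sum(lv * qm)
  sd_p <- sqrt(sum((lv - mu_p)^2 * pm))
  sd_q <- sqrt(sum((lv - mu_q)^2 * qm))
  if (sd_p == 0 || sd_q == 0) return(NA_real_)
  cross <- sum(outer(lv, lv) * M$mat)
  (cross - mu_p * mu_q) / (sd_p * sd_q)
}

#' @rdname glcm-features
#' @export
glcm_homogeneity <- function(M) {
  assert_glcm(M)
  G <- M$n_levels
  p <- matrix(0:(G - 1L), G, G)
  q <- t(p)
  sum(M$mat / (1 + (p - q)^2))
}

#' @rdname glcm-features
#' @export
glcm_entropy <- function(M) {
  assert_glcm(M)
  f <- M$mat[M$mat > 0]
  -sum(f * log2(f))
}

# the five features in canonical order; COR sentinel handling is the
# caller's choice
glcm_features <- function(M, cor_sentinel = NA_real_) {
  cor <- glcm_correlation(M)
  c(CON = glcm_contrast(M),
    COR = if (is.na(cor)) cor_sentinel else cor,
    ENE = glcm_energy(M),
    HOM = glcm_homogeneity(M),
    ENT = glcm_entropy(M))
}

#' GLCM feature vector over wavelet subbands
#'
#' For each selected subband: quantize the coefficients to `G` levels,
#' build one GLCM per requested angle, compute the five texture features
#' (contrast, correlation, energy, homogeneity, entropy), and either
#' average them over angles (`aggregate = "mean"`, default) or keep one
#' entry per angle. The output is ordered by level ascending, `LL` before
#' `HL`, features in the fixed order CON, COR, ENE, HOM, ENT. An undefined
#' correlation (zero marginal variance, e.g. a constant subband) is
#' reported as 0 with a warning so it cannot poison classifier input.
#'
#' @param subbands Output of [select_subbands()], or a single numeric
#'   matrix (treated as level 1, band `LL`).
#' @param G Gray levels for quantization (default 8).
#' @param S Co-occurrence distance (default 1).
#' @param angles Angles in degrees (default `c(0, 45, 90, 135)`).
#' @param aggregate `"mean"` (default) or `"per_angle"`.
#' @param symmetric Symmetric GLCM (default TRUE).
#' @return Named numeric vector; names are `L<level>.<band>.<FEATURE>`
#'   (with an `.a<angle>` suffix when `aggregate = "per_angle"`).
#' @export
feature_vector <- function(subbands, G = 8L, S = 1L,
                           angles = c(0, 45, 90, 135),
                           aggregate = c("mean", "per_angle"),
                           symmetric = TRUE) {
  aggregate <- match.arg(aggregate)
  if (is.matrix(subbands))
    subbands <- list(L1.LL = list(level = 1L, band = "LL",
                                  coefficients = subbands))
  if (!is.list(subbands) || length(subbands) == 0L)
    abort_validation("subbands must be a non-empty subband list")
  if (length(angles) == 0L) abort_validation("need at least one angle")
  out <- numeric(0)
  warned <- FALSE
  for (sb in subbands) {
    q <- quantize(sb$coefficients, G)
    per_angle <- sapply(angles, function(a) {
      M <- glcm(q, S = S, angle = a, symmetric = symmetric, n_levels = G)
      glcm_features(M)
    })                                       # 5 x n_angles
    if (anyNA(per_angle)) {
      if (!warned) {
        warning("undefined GLCM correlation (zero marginal variance) ",
                "reported as 0", call. = FALSE)
        warned <- TRUE
      }
      per_angle[is.na(per_angle)] <- 0
    }
    key <- sprintf("L%d.%s", sb$level, sb$band)
    if (aggregate == "mean") {
      v <- rowMeans(per_angle)
      names(v) <- paste(key, c("CON", "COR", "ENE", "HOM", "ENT"),
                        sep = ".")
      out <- c(out, v)
    } else {
      for (ai in seq_along(angles)) {
        v <- per_angle[, ai]
        names(v) <- paste(key, c("CON", "COR", "ENE", "HOM", "ENT"),
                          paste0("a", angles[ai]), sep = ".")
        out <- c(out, v)
      }
    }
  }
  out
}
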