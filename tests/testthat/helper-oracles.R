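# Independent brute-force oracles. Each re-derives the expected result by
# direct enumeration, sharing no code with the implementation under test.

rand_gray <- function(r, c, levels = 256L) {
  gray_image(matrix(sample.int(levels, r * c, replace = TRUE) - 1L, r, c))
}

# per-pixel sorted-neighborhood median with edge replication
oracle_median <- function(m, w) {
  h <- (w - 1L) %/% 2L
  r <- nrow(m); cl <- ncol(m)
  out <- m
  for (i in seq_len(r)) for (j in seq_len(cl)) {
    ri <- pmin(pmax((i - h):(i + h), 1L), r)
    ci <- pmin(pmax((j - h):(j + h), 1L), cl)
    v <- sort(as.vector(m[ri, ci]))
    out[i, j] <- v[(length(v) + 1L) %/% 2L]   # odd count: exact middle
  }
  out
}

glcm_offset_oracle <- function(angle, S) {
  switch(as.character(angle),
         "0" = c(0, S), "45" = c(-S, S), "90" = c(-S, 0), "135" = c(-S, -S))
}

# enumerate every ordered pixel pair at the offset (and its reverse when
# symmetric), returning the raw count matrix
oracle_glcm_counts <- function(q, S, angle, symmetric, G) {
  off <- glcm_offset_oracle(angle, S)
  counts <- matrix(0, G, G)
  for (i in seq_len(nrow(q))) for (j in seq_len(ncol(q))) {
    ni <- i + off[1]; nj <- j + off[2]
    if (ni >= 1 && ni <= nrow(q) && nj >= 1 && nj <= ncol(q)) {
      counts[q[i, j] + 1, q[ni, nj] + 1] <-
        counts[q[i, j] + 1, q[ni, nj] + 1] + 1
      if (symmetric)
        counts[q[ni, nj] + 1, q[i, j] + 1] <-
          counts[q[ni, nj] + 1, q[i, j] + 1] + 1
    }
  }
  counts
}

# the five texture statistics by explicit term-by-term summation
oracle_features <- function(f) {
  G <- nrow(f)
  con <- cor_num <- hom <- ent <- ene2 <- 0
  pm <- numeric(G); qm <- numeric(G)
  for (p in 1:G) for (q in 1:G) {
    v <- f[p, q]
    con <- con + (p - q)^2 * v
    hom <- hom + v / (1 + (p - q)^2)
    ene2 <- ene2 + v^2
    if (v > 0) ent <- ent - v * log2(v)
    pm[p] <- pm[p] + v
    qm[q] <- qm[q] + v
  }
  mu_p <- sum((0:(G - 1)) * pm); mu_q <- sum((0:(G - 1)) * qm)
  sd_p <- sqrt(sum(((0:(G - 1)) - mu_p)^2 * pm))
  sd_q <- sqrt(sum(((0:(G - 1)) - mu_q)^2 * qm))
  cross <- 0
  for (p in 1:G) for (q in 1:G)
    cross <- cross + (p - 1) * (q - 1) * f[p, q]
  cor <- if (sd_p == 0 || sd_q == 0) NA_real_
         else (cross - mu_p * mu_q) / (sd_p * sd_q)
  c(CON = con, COR = cor, ENE = sqrt(ene2), HOM = hom, ENT = ent)
}

# breadth-first flood fill accepting |v - seed mean| <= delta (fixed mean)
oracle_flood_fill <- function(px, seed, delta, connectivity = 4L) {
  r <- nrow(px); cl <- ncol(px)
  m0 <- px[seed[1], seed[2]]
  member <- matrix(FALSE, r, cl)
  member[seed[1], seed[2]] <- TRUE
  frontier <- list(seed)
  nb <- if (connectivity == 4L)
    list(c(-1, 0), c(0, -1), c(0, 1), c(1, 0))
  else list(c(-1, 0), c(0, -1), c(0, 1), c(1, 0),
            c(-1, -1), c(-1, 1), c(1, -1), c(1, 1))
  while (length(frontier) > 0) {
    p <- frontier[[1]]; frontier <- frontier[-1]
    for (d in nb) {
      ni <- p[1] + d[1]; nj <- p[2] + d[2]
      if (ni < 1 || ni > r || nj < 1 || nj > cl) next
      if (member[ni, nj]) next
      if (abs(px[ni, nj] - m0) <= delta) {
        member[ni, nj] <- TRUE
        frontier[[length(frontier) + 1]] <- c(ni, nj)
      }
    }
  }
  member
}

# per-pixel max/min filter over the footprint
oracle_dilate <- function(m, footprint, origin) {
  r <- nrow(m); cl <- ncol(m)
  out <- matrix(FALSE, r, cl)
  offs <- which(footprint, arr.ind = TRUE)
  for (i in seq_len(r)) for (j in seq_len(cl)) {
    hit <- FALSE
    for (k in seq_len(nrow(offs))) {
      # reflected footprint overlapping any true input cell
      si <- i - (offs[k, 1] - origin[1]); sj <- j - (offs[k, 2] - origin[2])
      if (si >= 1 && si <= r && sj >= 1 && sj <= cl && m[si, sj])
        hit <- TRUE
    }
    out[i, j] <- hit
  }
  out
}

oracle_erode <- function(m, footprint, origin) {
  r <- nrow(m); cl <- ncol(m)
  out <- matrix(FALSE, r, cl)
  offs <- which(footprint, arr.ind = TRUE)
  for (i in seq_len(r)) for (j in seq_len(cl)) {
    all_in <- TRUE
    for (k in seq_len(nrow(offs))) {
      si <- i + (offs[k, 1] - origin[1]); sj <- j + (offs[k, 2] - origin[2])
      if (si < 1 || si > r || sj < 1 || sj > cl || !m[si, sj])
        all_in <- FALSE
    }
    out[i, j] <- all_in
  }
  out
}

# 1-nearest-neighbor on standardized coordinates; ties to earliest pattern
oracle_nn <- function(patterns, labels, z) {
  d2 <- rowSums(sweep(patterns, 2, z, "-")^2)
  labels[which.min(d2)]
}

# build a pnn whose stored patterns are taken verbatim (identity
# standardization), for checks stated directly on standardized inputs
pnn_raw <- function(patterns, labels, sigma, classes = NULL) {
  fit <- suppressWarnings(pnn(patterns, labels, sigma = sigma,
                              classes = classes))
  fit$patterns <- as.matrix(patterns)
  fit$center <- rep(0, ncol(fit$patterns))
  fit$scale <- rep(1, ncol(fit$patterns))
  fit
}

pad_mask <- function(m, w) {
  out <- matrix(FALSE, nrow(m) + 2 * w, ncol(m) + 2 * w)
  out[w + seq_len(nrow(m)), w + seq_len(ncol(m))] <- m
  out
}

reflect_se <- function(se) {
  fp <- se$footprint[rev(seq_len(nrow(se$footprint))),
                     rev(seq_len(ncol(se$footprint))), drop = FALSE]
  structuring_element("custom", footprint = fp,
                      origin = c(nrow(fp) - se$origin[1] + 1,
                                 ncol(fp) - se$origin[2] + 1))
}
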