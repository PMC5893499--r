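worked_q <- rbind(c(0L, 0L, 1L, 1L),
                  c(0L, 0L, 1L, 1L),
                  c(0L, 2L, 2L, 2L),
                  c(2L, 2L, 3L, 3L))

test_that("quantize bins uniformly and degrades gracefully", {
  expect_true(all(quantize(matrix(3.7, 4, 4), 8) == 0L))

  img <- matrix(as.numeric(0:255), 16, 16)
  q <- quantize(img, 8)
  expect_identical(q, matrix(pmin(as.integer(img %/% 32), 7L), 16, 16))

  # exactly G equally spaced values relabel to 0..G-1
  vals <- matrix(rep(seq(10, 40, by = 10), each = 4), 4, 4)
  expect_identical(quantize(vals, 4),
                   matrix(rep(0:3, each = 4), 4, 4))
  expect_error(quantize(matrix(1, 2, 2), 1), "G")
})

test_that("co-occurrence counts match brute-force pair enumeration", {
  M <- glcm(worked_q, S = 1, angle = 0, symmetric = TRUE)
  expect_equal(sum(M$counts), 24)
  expect_equal(M$counts[1, 1], 4)
  expect_equal(M$counts[3, 3], 6)
  expect_equal(M$counts,
               oracle_glcm_counts(worked_q, 1, 0, TRUE, 4))
  expect_equal(sum(M$mat), 1, tolerance = 1e-12)

  # constant image: all mass in one cell
  Mc <- glcm(matrix(0L, 3, 3), 1, 45)
  expect_equal(Mc$mat[1, 1], 1)

  expect_error(glcm(matrix(0L, 2, 2), S = 5, angle = 0), "too small")
})

test_that("the worked GLCM yields the hand-derived feature values", {
  M <- glcm(worked_q, S = 1, angle = 0, symmetric = TRUE)
  expect_equal(glcm_contrast(M), 14 / 24)
  expect_equal(glcm_homogeneity(M), 19.4 / 24)
  expect_equal(glcm_energy(M), sqrt(84 / 576))
  o <- oracle_features(M$mat)
  expect_equal(glcm_entropy(M), unname(o["ENT"]))
  expect_equal(glcm_correlation(M), unname(o["COR"]))
})

test_that("feature extremes hold: checkerboard, diagonal, constant", {
  cb <- outer(1:8, 1:8, function(i, j) (i + j) %% 2L)   # checkerboard
  Mcb <- glcm(cb, 1, 0)
  expect_equal(glcm_contrast(Mcb), 1.0)
  expect_equal(glcm_homogeneity(Mcb), 0.5)

  # rows of constant value: horizontal pairs all (v, v) -> correlation 1
  diag_q <- matrix(rep(0:3, times = 4), 4, 4, byrow = TRUE)
  Md <- glcm(t(diag_q), 1, 0)
  expect_equal(glcm_contrast(Md), 0)
  expect_equal(glcm_correlation(Md), 1.0)

  Mc <- glcm(matrix(5L, 4, 4), 1, 0, n_levels = 8)
  expect_equal(glcm_contrast(Mc), 0)
  expect_equal(glcm_energy(Mc), 1.0)
  expect_equal(glcm_homogeneity(Mc), 1.0)
  expect_equal(glcm_entropy(Mc), 0)
  expect_true(is.na(glcm_correlation(Mc)))
})

test_that("all five features match the enumeration oracle on random images", {
  set.seed(808)
  for (i in 1:10) {
    q <- matrix(sample(0:7, 256, TRUE), 16, 16)
    for (a in c(0, 45, 90, 135)) {
      M <- glcm(q, 1, a, symmetric = TRUE, n_levels = 8)
      counts <- oracle_glcm_counts(q, 1, a, TRUE, 8)
      expect_equal(M$counts, counts)
      o <- oracle_features(counts / sum(counts))
      expect_equal(glcm_contrast(M), unname(o["CON"]), tolerance = 1e-10)
      expect_equal(glcm_correlation(M), unname(o["COR"]), tolerance = 1e-10)
      expect_equal(glcm_energy(M), unname(o["ENE"]), tolerance = 1e-10)
      expect_equal(glcm_homogeneity(M), unname(o["HOM"]), tolerance = 1e-10)
      expect_equal(glcm_entropy(M), unname(o["ENT"]), tolerance = 1e-10)
    }
  }
})

test_that("generated matrices are normalized and symmetric when asked", {
  set.seed(3)
  q <- matrix(sample(0:5, 100, TRUE), 10, 10)
  for (a in c(0, 45, 90, 135)) {
    M <- glcm(q, 1, a, symmetric = TRUE, n_levels = 6)
    expect_true(all(M$mat >= 0))
    expect_equal(sum(M$mat), 1, tolerance = 1e-12)
    expect_equal(M$mat, t(M$mat))
    Ma <- glcm(q, 1, a, symmetric = FALSE, n_levels = 6)
    expect_equal(sum(Ma$mat), 1, tolerance = 1e-12)
  }
})

test_that("feature_vector orders subbands and aggregates over angles", {
  set.seed(21)
  dec <- dwt2(matrix(runif(32 * 32, 0, 255), 32, 32), "haar", 2)
  sel <- select_subbands(dec, 1:2, c("LL", "HL"))
  fv <- feature_vector(sel, G = 8)
  expect_length(fv, 20)
  expect_equal(names(fv)[1:5],
               paste("L1.LL", c("CON", "COR", "ENE", "HOM", "ENT"),
                     sep = "."))
  expect_equal(names(fv)[16:20],
               paste("L2.HL", c("CON", "COR", "ENE", "HOM", "ENT"),
                     sep = "."))

  # mean aggregation equals the mean of independent per-angle features
  arr <- matrix(runif(32 * 32), 32, 32)
  fv1 <- feature_vector(arr, G = 8, aggregate = "mean")
  q <- quantize(arr, 8)
  per <- sapply(c(0, 45, 90, 135), function(a) {
    counts <- oracle_glcm_counts(q, 1, a, TRUE, 8)
    oracle_features(counts / sum(counts))
  })
  expect_equal(unname(fv1), unname(rowMeans(per)), tolerance = 1e-10)

  fv4 <- feature_vector(arr, G = 8, aggregate = "per_angle")
  expect_length(fv4, 20)
  expect_equal(unname(fv4[1:5]), unname(per[, 1]), tolerance = 1e-10)
})

test_that("constant subbands give the degenerate feature identities", {
  expect_warning(fv <- feature_vector(matrix(1, 8, 8), G = 8),
                 "correlation")
  expect_equal(unname(fv),
               c(0, 0, 1, 1, 0))
})

test_that("features are invariant to a uniform intensity shift", {
  set.seed(9)
  arr <- matrix(runif(64, 0, 100), 8, 8)
  expect_identical(quantize(arr, 8), quantize(arr + 17.3, 8))
  expect_equal(feature_vector(arr), feature_vector(arr + 17.3))
})
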