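test_that("region growing covers constant images and respects delta", {
  const <- gray_image(matrix(7L, 5, 5))
  m <- grow_region(const, c(3, 3), delta = 0)
  expect_true(all(m))

  img <- gray_image(matrix(c(10L, 10L, 50L,
                             10L, 10L, 50L,
                             10L, 10L, 50L), 3, 3, byrow = TRUE))
  m <- grow_region(img, c(1, 1), delta = 5, connectivity = 4)
  expect_identical(unclass(m), cbind(matrix(TRUE, 3, 2), rep(FALSE, 3)))

  expect_error(grow_region(img, c(0, 1)), "bounds")
  expect_error(grow_region(img, c(1, 1), delta = -1), "delta")
})

test_that("fixed-mean growing equals an independent BFS flood fill", {
  set.seed(202)
  for (i in 1:5) {
    img <- rand_gray(32, 32, levels = 8L)
    seed_idx <- which(img$pixels == max(img$pixels), arr.ind = TRUE)[1, ]
    got <- grow_region(img, seed_idx, delta = 1, connectivity = 4,
                       mean_mode = "fixed")
    want <- oracle_flood_fill(img$pixels, seed_idx, delta = 1)
    expect_identical(unclass(got), want)
  }
})

test_that("growing yields one connected component containing all seeds", {
  set.seed(17)
  for (i in 1:5) {
    img <- rand_gray(24, 24, levels = 16L)
    seed <- c(sample(24, 1), sample(24, 1))
    m <- grow_region(img, seed, delta = 30, connectivity = 8)
    expect_true(m[seed[1], seed[2]])
    # every member must be reachable from the seed within the mask
    reach <- oracle_flood_fill(ifelse(unclass(m), 1, 99),
                               seed, delta = 0, connectivity = 8L)
    expect_identical(reach, unclass(m))
  }
  # adjacent seeds are members even when delta excludes their intensities
  img <- gray_image(matrix(c(0L, 255L, 0L, 0L), 2, 2))
  m <- grow_region(img, rbind(c(1, 1), c(1, 2)), delta = 0)
  expect_true(m[1, 1] && m[1, 2])
  # infinite tolerance floods the whole (connected) image
  img <- rand_gray(10, 10)
  expect_true(all(grow_region(img, c(5, 5), delta = Inf)))
})

test_that("running-mean growing is deterministic and order-stable", {
  set.seed(33)
  img <- rand_gray(20, 20, levels = 32L)
  a <- grow_region(img, c(10, 10), delta = 12, mean_mode = "running")
  b <- grow_region(img, c(10, 10), delta = 12, mean_mode = "running")
  expect_identical(unclass(a), unclass(b))
})

test_that("dilation and erosion match per-pixel footprint oracles", {
  single <- matrix(FALSE, 5, 5); single[3, 3] <- TRUE
  se <- structuring_element("square", 3)
  expect_identical(unclass(dilate(binary_mask(single), se)),
                   oracle_dilate(single, se$footprint, se$origin))
  expect_equal(region_area(dilate(binary_mask(single), se)), 9L)

  empty <- binary_mask(matrix(FALSE, 4, 4))
  expect_true(!any(dilate(empty, se)))

  block <- matrix(FALSE, 5, 5); block[2:4, 2:4] <- TRUE
  er <- erode(binary_mask(block), se)
  expect_identical(which(unclass(er)), which(single))

  allm <- binary_mask(matrix(TRUE, 5, 5))
  er_all <- erode(allm, se)
  expect_true(all(er_all[2:4, 2:4]))
  expect_true(!any(er_all[c(1, 5), ]) && !any(er_all[, c(1, 5)]))

  cross <- structuring_element("cross", 3)
  set.seed(404)
  for (i in 1:5) {
    m <- matrix(runif(256) < 0.4, 16, 16)
    expect_identical(unclass(dilate(binary_mask(m), cross)),
                     oracle_dilate(m, cross$footprint, cross$origin))
    expect_identical(unclass(erode(binary_mask(m), cross)),
                     oracle_erode(m, cross$footprint, cross$origin))
  }
})

test_that("erosion is the complement-dual of dilation on a padded domain", {
  set.seed(7)
  ses <- list(structuring_element("square", 3),
              structuring_element("cross", 3),
              structuring_element("custom",
                                  footprint = matrix(c(TRUE, TRUE, FALSE,
                                                       TRUE, TRUE, TRUE),
                                                     2, 3, byrow = TRUE),
                                  origin = c(1, 2)))
  for (se in ses) for (i in 1:5) {
    m <- matrix(runif(144) < 0.5, 12, 12)
    p <- pad_mask(m, 4)
    lhs <- unclass(erode(binary_mask(p), se))
    rhs <- !unclass(dilate(binary_mask(!p), reflect_se(se)))
    inner <- 5:16
    expect_identical(lhs[inner, inner], rhs[inner, inner])
  }
})

test_that("dilation never shrinks area and erosion never grows it", {
  set.seed(55)
  se <- structuring_element("square", 3)
  for (i in 1:10) {
    m <- binary_mask(matrix(runif(100) < 0.5, 10, 10))
    expect_gte(region_area(dilate(m, se)), region_area(m))
    expect_lte(region_area(erode(m, se)), region_area(m))
  }
})

test_that("clean_mask opens, filters small components, keeps the largest", {
  m <- matrix(FALSE, 20, 20)
  m[5:14, 5:14] <- TRUE                  # 10x10 block
  m[18, 18] <- TRUE                      # isolated speckle
  out <- clean_mask(binary_mask(m), min_component_px = 5)
  expect_false(out[18, 18])
  expect_true(all(out[6:13, 6:13]))

  expect_true(!any(clean_mask(binary_mask(matrix(FALSE, 6, 6)))))

  two <- matrix(FALSE, 24, 24)
  two[3:10, 3:10] <- TRUE                # survives opening as 8x8 = 64 px
  two[16:20, 16:21] <- TRUE              # 5x6 block
  se1 <- structuring_element("square", 1)  # opening is identity; pure filter
  out <- clean_mask(binary_mask(two), se1, min_component_px = 40)
  expect_identical(which(unclass(out)), which(two & row(two) <= 10))
})

test_that("cleanup is idempotent", {
  set.seed(99)
  for (i in 1:10) {
    m <- binary_mask(matrix(runif(400) < 0.55, 20, 20))
    once <- clean_mask(m, min_component_px = 10)
    twice <- clean_mask(once, min_component_px = 10)
    expect_identical(unclass(once), unclass(twice))
  }
})

test_that("region_area counts foreground cells", {
  expect_equal(region_area(binary_mask(matrix(FALSE, 16, 16))), 0L)
  rect <- matrix(FALSE, 6, 6); rect[2:4, 2:5] <- TRUE
  expect_equal(region_area(binary_mask(rect)), 12L)
  set.seed(1)
  m <- matrix(runif(64) < 0.3, 8, 8)
  expect_equal(region_area(binary_mask(m)), sum(sapply(seq_len(64), function(i) m[i])))
})

test_that("auto_seed lands on the bright structure", {
  img_px <- matrix(10L, 32, 32)
  img_px[10:15, 20:25] <- 200L
  s <- auto_seed(gray_image(img_px))
  expect_true(s[1] >= 10 && s[1] <= 15 && s[2] >= 20 && s[2] <= 25)
})
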