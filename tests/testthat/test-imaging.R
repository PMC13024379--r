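test_that("rg_composite averages red and green and ignores blue", {
  expect_equal(rg_composite(uniform_rgb(3, 3, c(100, 200, 50)))$pixels[1, 1], 150L)
  expect_equal(rg_composite(uniform_rgb(3, 3, c(0, 0, 255)))$pixels[2, 2], 0L)

  img <- uniform_rgb(5, 7, c(60, 80, 7))
  comp <- rg_composite(img)
  # per-pixel oracle over all pixels
  expected <- floor((img$pixels[, , 1] + img$pixels[, , 2]) / 2 + 0.5)
  expect_true(all(comp$pixels == expected))
  expect_true(all(comp$pixels == 70L))
  expect_equal(dim(comp$pixels), c(5, 7))
  expect_identical(comp$provenance, "composite")

  expect_error(rg_composite(list(pixels = NULL)), "rgb_raster")
})

test_that("enhance_contrast stretches percentile anchors to 0 and 255", {
  # constant image: degenerate stretch returns input unchanged
  const <- gray_raster(matrix(77L, 4, 4))
  expect_equal(enhance_contrast(const)$pixels, const$pixels)

  # build a plane whose 1st/99th percentiles are exactly 50 and 150
  vals <- c(rep(50L, 300), rep(100L, 300), rep(150L, 300))
  g <- gray_raster(matrix(vals, 30, 30))
  out <- enhance_contrast(g)$pixels
  expect_equal(out[g$pixels == 50L][1], 0L)
  expect_equal(out[g$pixels == 150L][1], 255L)
  expect_equal(out[g$pixels == 100L][1], 128L)  # round(255 * 50/100)

  # clipping outside the anchors
  vals2 <- c(10L, rep(50L, 400), rep(150L, 400), 250L, rep(100L, 98))
  g2 <- gray_raster(matrix(vals2, 30, 30))
  out2 <- enhance_contrast(g2, p_low = 5, p_high = 95)$pixels
  expect_equal(out2[g2$pixels == 10L][1], 0L)
  expect_equal(out2[g2$pixels == 250L][1], 255L)

  expect_error(enhance_contrast(g, p_low = 60, p_high = 40), "p_low")
})

test_that("calibrate_threshold places the cut midway between class means", {
  m <- calibrate_threshold(c(180, 190, 200), c(40, 50, 60))
  expect_equal(m$threshold, 120)
  expect_equal(m$bead_level, 190)
  expect_equal(m$electrode_level, 50)
  expect_equal(m$n_bead, 3L)

  expect_equal(calibrate_threshold(200, 0)$threshold, 100)
  expect_error(calibrate_threshold(100, 100), "separable")
  expect_error(calibrate_threshold(numeric(0), 50), "at least one sample")
})

test_that("binarize labels the bead side of the threshold", {
  model <- calibrate_threshold(c(180, 200), c(40, 60))  # bead brighter, cut 120
  g <- gray_raster(matrix(c(130L, 119L, 120L, 0L), 2, 2))
  mask <- binarize(g, model)
  expect_true(mask$pixels[1, 1])    # 130 >= 120
  expect_false(mask$pixels[2, 1])   # 119 < 120
  expect_true(mask$pixels[1, 2])    # boundary value belongs to bead class

  # inverted polarity: bead class darker
  dark_model <- calibrate_threshold(c(20, 40), c(200, 220))
  inv <- binarize(g, dark_model)
  expect_false(inv$pixels[1, 1])
  expect_true(inv$pixels[2, 2])

  # all below threshold -> all background
  low <- binarize(gray_raster(matrix(10L, 3, 3)), model)
  expect_false(any(low$pixels))

  expect_error(binarize(g, model, roi = c(0, 0, 5, 5)), "bounds")
})

test_that("coverage is the bead area fraction of the ROI", {
  all_bead <- binary_mask(matrix(TRUE, 4, 4))
  expect_equal(coverage(all_bead), 100)
  expect_equal(coverage(binary_mask(matrix(FALSE, 4, 4))), 0)

  px <- matrix(FALSE, 3, 4)
  px[c(1, 5, 9)] <- TRUE  # 3 bead pixels of 12
  expect_equal(coverage(binary_mask(px)), 25)

  # ROI restriction counts only inside the rectangle
  m <- binary_mask(matrix(TRUE, 6, 6), roi = c(0, 0, 3, 3))
  m$pixels[1:3, 1:3] <- FALSE
  expect_equal(coverage(m), 0)
})

test_that("coverage matches the brute-force pixel count on random masks", {
  set.seed(42)
  for (i in 1:200) {
    h <- sample(3:64, 1); w <- sample(3:64, 1)
    mask <- random_mask(h, w, p = runif(1))
    expect_identical(coverage(mask), coverage_oracle(mask))
  }
})

test_that("flipping a background pixel to bead strictly increases coverage", {
  set.seed(7)
  for (i in 1:20) {
    mask <- random_mask(8, 8, p = 0.4)
    bg <- which(!mask$pixels)
    if (length(bg) == 0) next
    j <- sample(bg, 1)
    flipped <- mask
    flipped$pixels[j] <- TRUE
    expect_gt(coverage(flipped), coverage(mask))
  }
})

test_that("grid_uniformity computes the population SD over 3x3 cells", {
  # all cells equal -> sd 0
  u0 <- grid_uniformity(binary_mask(matrix(TRUE, 6, 6)))
  expect_equal(u0$sd, 0)
  expect_equal(u0$cell_coverages, rep(100, 9))

  # construct a mask whose 9 cells have coverages {10,...,10,100}:
  # 30x30 ROI, 10x10 cells; 10 bead pixels in eight cells, 100 in the last
  px <- matrix(FALSE, 30, 30)
  for (i in 0:2) for (j in 0:2) {
    cell_cov <- if (i == 2 && j == 2) 100 else 10
    rows <- (i * 10 + 1):(i * 10 + 10)
    cols <- (j * 10 + 1):(j * 10 + 10)
    idx <- which(matrix(TRUE, 10, 10))[seq_len(cell_cov)]
    sub <- matrix(FALSE, 10, 10); sub[idx] <- TRUE
    px[rows, cols] <- sub
  }
  u <- grid_uniformity(binary_mask(px))
  expect_equal(sort(u$cell_coverages), c(rep(10, 8), 100))
  expect_equal(u$sd, sqrt(800))  # mean 20, mean squared deviation 800
  expect_equal(u$sd, grid_sd_oracle(u$cell_coverages))

  expect_error(grid_uniformity(binary_mask(matrix(TRUE, 4, 4),
                                           roi = c(0, 0, 2, 2))), "3x3")
})

test_that("grid SD is permutation-invariant and tiles the ROI coverage", {
  set.seed(11)
  for (i in 1:20) {
    mask <- random_mask(12, 15, p = runif(1, 0.1, 0.9))  # divisible by 3
    u <- grid_uniformity(mask)
    # partition identity: mean of cell coverages equals ROI coverage exactly
    expect_equal(u$mean_coverage, coverage(mask))
    # SD from any permutation of the cells is identical
    expect_equal(grid_sd_oracle(sample(u$cell_coverages)), u$sd)
    expect_identical(u$sd == 0, length(unique(u$cell_coverages)) == 1L)
  }
})

test_that("grid trimming keeps the nine sub-areas exactly equal", {
  # 10x11 ROI trims to 9x9; plant beads only in the trimmed margin
  px <- matrix(FALSE, 10, 11)
  px[10, ] <- TRUE
  px[, 10:11] <- TRUE
  u <- grid_uniformity(binary_mask(px))
  expect_equal(u$cell_coverages, rep(0, 9))
  expect_equal(u$sd, 0)
})

test_that("axial_profile bins coverage along the flow axis from the inlet", {
  # uniform mask: every bin equals the global coverage
  set.seed(29)
  mask40 <- binary_mask(matrix(runif(8 * 40) < 0.4, 8, 40))
  uni <- binary_mask(matrix(TRUE, 8, 40))
  p <- axial_profile(uni, n_bins = 8)
  expect_equal(p$coverages, rep(100, 8))

  # beads only in the inlet half
  half <- matrix(FALSE, 6, 20)
  half[, 1:10] <- TRUE
  p2 <- axial_profile(binary_mask(half), n_bins = 2)
  expect_equal(p2$coverages, c(100, 0))
  expect_equal(p2$bin_centers, c(5, 15))
  expect_true(all(diff(p2$bin_centers) > 0))

  # contract: length n_bins, values in [0, 100]
  p3 <- axial_profile(mask40, n_bins = 7)
  expect_length(p3$coverages, 7)
  expect_true(all(p3$coverages >= 0 & p3$coverages <= 100))

  # n_bins = 1 equals coverage of the trimmed ROI (here untrimmed)
  expect_equal(axial_profile(mask40, n_bins = 1)$coverages, coverage(mask40))

  expect_error(axial_profile(uni, n_bins = 41), "exceeds")
})

test_that("axial_profile trims excess columns on the outlet side", {
  # 23 columns, 4 bins -> band width 5, columns 21:23 trimmed
  px <- matrix(FALSE, 5, 23)
  px[, 21:23] <- TRUE  # beads only in the trimmed tail
  p <- axial_profile(binary_mask(px), n_bins = 4)
  expect_equal(p$coverages, rep(0, 4))
  # n_bins = 1 on the same mask trims nothing (band width 23)
  expect_equal(axial_profile(binary_mask(px), n_bins = 1)$coverages,
               100 * 3 / 23)
})

test_that("profile_deviation is the mean absolute per-bin difference", {
  mk <- function(covs) structure(
    list(n_bins = length(covs), bin_centers = seq_along(covs) - 0.5,
         coverages = covs), class = "axial_profile")

  expect_equal(as.numeric(profile_deviation(mk(c(50, 50)), mk(c(50, 50)))), 0)
  expect_equal(as.numeric(profile_deviation(mk(c(50, 50)), mk(c(50, 40)))), 5)
  d <- profile_deviation(mk(c(30, 50)), mk(c(40, 40)))
  expect_equal(as.numeric(d), 10)
  expect_equal(attr(d, "signed_mean"), 0)  # +10 and -10 cancel in sign

  expect_error(profile_deviation(mk(c(1, 2)), mk(c(1, 2, 3))), "incompatible")
})

test_that("profile_deviation is symmetric and satisfies the triangle inequality", {
  mk <- function(covs) structure(
    list(n_bins = length(covs), bin_centers = seq_along(covs) - 0.5,
         coverages = covs), class = "axial_profile")
  set.seed(3)
  for (i in 1:25) {
    a <- mk(runif(10, 0, 100)); b <- mk(runif(10, 0, 100))
    cc <- mk(runif(10, 0, 100))
    expect_equal(as.numeric(profile_deviation(a, b)),
                 as.numeric(profile_deviation(b, a)))
    expect_lte(as.numeric(profile_deviation(a, cc)),
               as.numeric(profile_deviation(a, b)) +
                 as.numeric(profile_deviation(b, cc)) + 1e-12)
  }
})

test_that("calibrated binarization perfectly separates non-overlapping classes", {
  set.seed(19)
  for (i in 1:10) {
    truth <- matrix(runif(40 * 60) < 0.35, 40, 60)
    gray <- matrix(0L, 40, 60)
    gray[truth] <- sample(160:220, sum(truth), replace = TRUE)
    gray[!truth] <- sample(30:90, sum(!truth), replace = TRUE)
    g <- gray_raster(gray)
    model <- calibrate_threshold(gray[truth][1:50], gray[!truth][1:50])
    mask <- binarize(g, model)
    expect_identical(mask$pixels, truth)  # 100% pixel accuracy
  }
})
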