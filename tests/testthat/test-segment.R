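test_that("segmentation recovers an ideal disk", {
  n <- 128
  img <- disk_mask(n, 50) * 1.0
  reg <- segment_region(img, blur_sigma = 1)
  expect_lt(abs(sum(reg$mask) - pi * 50^2) / (pi * 50^2), 0.05)
  c0 <- (n - 1) / 2
  rb <- sqrt((reg$boundary[, 1] - c0)^2 + (reg$boundary[, 2] - c0)^2)
  expect_lt(max(abs(rb - 50)), 1.5)
  expect_equal(unname(reg$centroid), c(c0, c0), tolerance = 0.02)
})

test_that("constant image is rejected and largest component is kept", {
  expect_error(segment_region(matrix(1, 32, 32)), "no region")
  img <- matrix(0, 100, 100)
  img[disk_mask(100, 30)] <- 1
  xg <- matrix(0:99, 100, 100, byrow = TRUE); yg <- t(xg)
  small <- (xg - 88)^2 + (yg - 88)^2 <= 5^2
  img[small] <- 1
  reg <- segment_region(img, blur_sigma = 1)
  expect_false(any(reg$mask[small & !disk_mask(100, 30)]))
  expect_gt(sum(reg$mask), 0.8 * pi * 30^2)
})

test_that("boundary extraction gives the 8-connected rim", {
  m <- matrix(FALSE, 5, 5); m[2:4, 2:4] <- TRUE
  b <- extract_boundary(m)
  expect_equal(nrow(b), 8)          # 3x3 square: all but the centre
  expect_false(any(b[, 1] == 2 & b[, 2] == 2))
  one <- matrix(FALSE, 3, 3); one[2, 2] <- TRUE
  expect_equal(unname(extract_boundary(one)), matrix(c(1L, 1L), 1))
  bd <- extract_boundary(disk_mask(128, 50))
  expect_lt(abs(nrow(bd) - 2 * pi * 50) / (2 * pi * 50), 0.15)
  expect_error(extract_boundary(matrix(FALSE, 3, 3)), "foreground")
})

test_that("distance to boundary matches geometry and brute force", {
  reg <- region_from_mask(disk_mask(128, 50))
  c0 <- 127 / 2
  expect_equal(distance_to_boundary(cbind(c0, c0), reg), 50, tolerance = 0.02)
  bpix <- reg$boundary[10, , drop = FALSE]
  expect_equal(distance_to_boundary(bpix, reg), 0)
  set.seed(4)
  idx <- which(reg$mask, arr.ind = TRUE)
  pick <- idx[sample(nrow(idx), 200), ]
  xy <- cbind(pick[, 2] - 1 + runif(200, -0.4, 0.4),
              pick[, 1] - 1 + runif(200, -0.4, 0.4))
  expect_equal(distance_to_boundary(xy, reg), brute_min_dist(xy, reg$boundary),
               tolerance = 1e-12)
})

test_that("spots outside the mask are excluded, not errors", {
  reg <- region_from_mask(disk_mask(64, 20))
  d <- distance_to_boundary(rbind(c(1, 1), c(31.5, 31.5)), reg)
  expect_true(is.na(d[1]))
  expect_false(is.na(d[2]))
})

test_that("null sampling is uniform over the mask and reproducible", {
  reg <- region_from_mask(disk_mask(128, 50))
  d1 <- sample_null(reg, n_spots = 200, multiplier = 10, seed = 7)
  d2 <- sample_null(reg, n_spots = 200, multiplier = 10, seed = 7)
  expect_identical(d1, d2)
  expect_length(d1, 2000)
  expect_length(sample_null(reg, 0, multiplier = 5, seed = 1), 0)
  ## analytic annulus check: P(r/r0 <= 0.1) = 1 - 0.9^2 = 0.19 on a disk
  ## (large disk so pixelation bias is below the Monte Carlo error)
  big <- region_from_mask(disk_mask(256, 110))
  d <- sample_null(big, n_spots = 1000, multiplier = 100, seed = 11)
  frac <- mean(d / big$r0 <= 0.1)
  expect_lt(abs(frac - 0.19), 3 * sqrt(0.19 * 0.81 / length(d)) + 0.015)
})

test_that("spot detection localises emitters to sub-pixel accuracy", {
  ## ten well-separated emitters with known sub-pixel positions
  set.seed(42)
  truth <- as.matrix(expand.grid(x = c(20, 45, 70, 95, 110),
                                 y = c(30, 90)))[, 1:2] +
    matrix(runif(20, -0.4, 0.4), 10, 2)
  img <- matrix(0, 128, 128)
  xg <- matrix(0:127, 128, 128, byrow = TRUE); yg <- t(xg)
  for (k in 1:10)
    img <- img + 1000 * exp(-((xg - truth[k, 1])^2 + (yg - truth[k, 2])^2) /
                            (2 * 1.5^2))
  spots <- detect_spots(img, min_separation = 4, threshold = 150)
  expect_equal(nrow(spots), 10)
  derr <- vapply(seq_len(nrow(spots)), function(i)
    min(sqrt((truth[, 1] - spots$x_px[i])^2 +
             (truth[, 2] - spots$y_px[i])^2)), 1.0)
  expect_lt(max(derr), 0.5)
})

test_that("blank images give empty tables and close emitters merge", {
  blank <- matrix(0, 64, 64)
  expect_equal(nrow(detect_spots(blank, threshold = 1)), 0)
  img <- matrix(0, 64, 64)
  xg <- matrix(0:63, 64, 64, byrow = TRUE); yg <- t(xg)
  for (p in list(c(30, 30), c(32, 30)))   # 2 px apart < min_separation
    img <- img + 500 * exp(-((xg - p[1])^2 + (yg - p[2])^2) / (2 * 1.5^2))
  spots <- detect_spots(img, min_separation = 4, threshold = 100)
  expect_equal(nrow(spots), 1)
})
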