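make_two_emitters <- function(n_frames = 40, gap_frames = NULL) {
  ## two well-separated, slowly jittering emitters; optional blink gap in
  ## the first one
  set.seed(101)
  f <- 0:(n_frames - 1)
  a <- data.frame(frame = f, x_um = 1 + rnorm(n_frames, 0, 0.02),
                  y_um = 1 + rnorm(n_frames, 0, 0.02))
  b <- data.frame(frame = f, x_um = 5 + rnorm(n_frames, 0, 0.02),
                  y_um = 5 + rnorm(n_frames, 0, 0.02))
  if (!is.null(gap_frames)) a <- a[!(a$frame %in% gap_frames), ]
  rbind(a, b)
}

test_that("linking separates well-spaced emitters into pure tracks", {
  spots <- make_two_emitters()
  tr <- link_spots(spots, max_disp = 0.5)
  expect_equal(length(unique(tr$id)), 2)
  ## identity purity: every localisation near (1,1) has one id
  id_a <- unique(tr$id[tr$x_um < 3])
  expect_length(id_a, 1)
  expect_equal(sum(tr$id == id_a), 40)
})

test_that("gap closing follows the memory parameter", {
  spots <- make_two_emitters(gap_frames = c(20, 21))
  tr3 <- link_spots(spots, max_disp = 0.5, memory = 3)
  expect_equal(length(unique(tr3$id)), 2)
  tr0 <- link_spots(spots, max_disp = 0.5, memory = 0)
  expect_equal(length(unique(tr0$id)), 3)  # the gapped track splits
})

test_that("COM tracking finds the centroid and its displacement", {
  img <- matrix(0, 80, 80)
  img[disk_mask(80, 20)] <- 100
  mov <- array(0, c(80, 80, 2))
  mov[, , 1] <- img
  mov[, , 2] <- rbind(cbind(matrix(0, 2, 1), matrix(0, 2, 79)),
                      cbind(matrix(0, 78, 1), img[1:78, 1:79]))
  com <- track_com(mov, blur_sigma = 1, pixel_size = 1)
  expect_equal(com$x_um[2] - com$x_um[1], 1, tolerance = 0.1)
  expect_equal(com$y_um[2] - com$y_um[1], 2, tolerance = 0.1)
})

test_that("g2 is zero for stationary emitters and exactly zero at lag 0", {
  f <- 0:49
  df <- rbind(data.frame(id = 1, frame = f, x_um = 1, y_um = 2),
              data.frame(id = 2, frame = f, x_um = 3, y_um = 4))
  tr <- track_set(df, frame_interval = 0.125)
  g <- g2_msd(tr)
  expect_equal(g$value[g$lag_s == 0], 0)
  expect_true(all(g$value < 1e-24))
})

test_that("g2 and dMSD are invariant under rigid translation drift", {
  out <- make_confined_tracks(6, kappa = 0.1, n_frames = 300, seed = 21)
  tr <- out$tracks
  g0 <- g2_msd(tr, com = NULL, max_lag = 50)
  d0 <- dmsd(tr, max_lag = 50)
  drift <- make_confined_tracks(6, kappa = 0.1, n_frames = 300, seed = 21,
                                drift = c(0.3, -0.2))
  g1 <- g2_msd(drift$tracks, max_lag = 50)  # uses the returned COM
  d1 <- dmsd(drift$tracks, max_lag = 50)
  expect_equal(g1$value, g0$value, tolerance = 1e-9)
  expect_equal(d1$curve$value, d0$curve$value, tolerance = 1e-9)
})

test_that("dMSD of rigidly comoving emitters vanishes; independent pairs add", {
  f <- 0:199
  set.seed(31)
  path_x <- cumsum(rnorm(200, 0, 0.1)); path_y <- cumsum(rnorm(200, 0, 0.1))
  df <- rbind(data.frame(id = 1, frame = f, x_um = path_x, y_um = path_y),
              data.frame(id = 2, frame = f, x_um = path_x + 2,
                         y_um = path_y + 1))
  rigid <- track_set(df, frame_interval = 0.125)
  expect_true(all(dmsd(rigid)$curve$value < 1e-24))
  free <- make_confined_tracks(30, kappa = 0, n_frames = 200, gamma = 0.1,
                               seed = 32)
  D <- kBT_pN_um(298) / 0.1
  d <- dmsd(free$tracks, max_lag = 20)
  lag <- d$curve$lag_s[d$curve$lag_s > 0]
  ratio <- d$curve$value[d$curve$lag_s > 0] / (8 * D * lag)
  expect_lt(max(abs(ratio[1:8] - 1)), 0.1)
})

test_that("pair-distance statistics recover imposed jitter", {
  sigma <- 0.05
  f <- 0:999
  set.seed(41)
  df <- rbind(data.frame(id = 1, frame = f, x_um = rnorm(1000, 0, sigma),
                         y_um = rnorm(1000, 0, sigma)),
              data.frame(id = 2, frame = f, x_um = rnorm(1000, 3, sigma),
                         y_um = rnorm(1000, 0, sigma)))
  tr <- track_set(df, frame_interval = 0.125)
  d <- dmsd(tr)
  expect_equal(d$pairs$mean_d, 3, tolerance = 0.02)
  ## Var(|d|) ~ 2 sigma^2 for jitter along the separation axis
  expect_equal(d$pairs$sd_d, sqrt(2) * sigma, tolerance = 0.1)
})

test_that("exponent fitting is exact on pure power laws", {
  lag <- (1:60) * 0.125
  mk <- function(v) structure(data.frame(lag_s = c(0, lag), value = c(0, v),
                                         n = rep(100, 61)),
                              kind = "g2", class = c("msd_curve", "data.frame"))
  f5 <- fit_exponent(mk(0.3 * lag^0.5))
  expect_equal(f5$alpha, 0.5, tolerance = 1e-10)
  f1 <- fit_exponent(mk(4 * 0.1 * lag))
  expect_equal(f1$alpha, 1, tolerance = 1e-10)
  expect_error(fit_exponent(mk(0.3 * lag^0.5), window = c(0.1, 0.3)), ">= 4")
  bad <- mk(c(-1, rep(1, 59)))
  expect_error(fit_exponent(bad), "nonpositive")
})

test_that("plateau estimation averages the tail and guards against growth", {
  lag <- (1:200) * 0.125
  mk <- function(v) structure(data.frame(lag_s = c(0, lag), value = c(0, v),
                                         n = rep(50, 201)),
                              kind = "g2", class = c("msd_curve", "data.frame"))
  p <- msd_plateau(mk(rep(0.2, 200)), t_min = 10)
  expect_equal(p$value, 0.2)
  expect_true(p$reliable)
  expect_warning(pr <- msd_plateau(mk(0.05 * lag), t_min = 10), "unreliable")
  expect_false(pr$reliable)
  expect_error(msd_plateau(mk(rep(0.2, 200)), t_min = 24.8), "fewer than 3")
})
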