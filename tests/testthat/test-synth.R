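test_that("zero emitters and no noise give an identically zero QD channel", {
  out <- make_kdna_image(0, shape = c(96, 96), noise = FALSE, seed = 1)
  expect_true(all(out$movie$qd == 0))
  expect_gt(max(out$movie$dna), 0)
})

test_that("a region larger than the frame is rejected", {
  expect_error(make_kdna_image(5, shape = c(40, 40), diameter_um = 4,
                               pixel_size = 0.07, seed = 1),
               "larger than frame")
})

test_that("peripheral law with all mass in the outer shell stays there", {
  out <- make_kdna_image(200, radial_law("peripheral", p_outer = 1,
                                         shell_fraction = 0.1),
                         noise = FALSE, seed = 3)
  expect_true(all(out$truth$r_over_r0 <= 0.1 + 1e-9))
})

test_that("uniform emitters reproduce the random-deposition null", {
  out <- make_kdna_image(3000, radial_law("uniform"), shape = c(128, 128),
                         noise = FALSE, seed = 5)
  reg <- out$truth$region
  r_true <- out$truth$r_over_r0 * reg$r0
  nul <- sample_null(reg, 3000, multiplier = 3, seed = 6)
  ks <- suppressWarnings(ks.test(r_true, nul))
  expect_gt(ks$p.value, 0.01)
})

test_that("image generation is bit-reproducible given the seed", {
  a <- make_kdna_image(8, shape = c(96, 96), seed = 12)
  b <- make_kdna_image(8, shape = c(96, 96), seed = 12)
  expect_identical(a$movie$qd, b$movie$qd)
  expect_identical(a$truth$positions_um, b$truth$positions_um)
})

test_that("confined tracks have the OU stationary variance", {
  kappa <- 0.1; temp <- 298
  out <- make_confined_tracks(6, kappa = kappa, temperature = temp,
                              n_frames = 4000, dt = 0.125, gamma = 0.02,
                              seed = 8)
  v_target <- kBT_pN_um(temp) / kappa
  for (id in 1:6) {
    tr <- out$tracks[out$tracks$id == id, ]
    v_emp <- (var(tr$x_um) + var(tr$y_um)) / 2
    expect_lt(abs(v_emp - v_target) / v_target, 0.35)
  }
  ## pooled estimate is tight
  v_all <- mean(vapply(1:6, function(id) {
    tr <- out$tracks[out$tracks$id == id, ]
    (var(tr$x_um) + var(tr$y_um)) / 2
  }, 1.0))
  expect_lt(abs(v_all - v_target) / v_target, 0.15)
})

test_that("kappa = 0 gives free diffusion with MSD = 4 D t", {
  temp <- 298; gamma <- 0.1
  out <- make_confined_tracks(200, kappa = 0, temperature = temp,
                              n_frames = 200, dt = 0.125, gamma = gamma,
                              seed = 9)
  D <- kBT_pN_um(temp) / gamma
  g <- g2_msd(out$tracks, com = NULL, max_lag = 40)
  lag <- g$lag_s[g$lag_s > 0]
  expect_lt(max(abs(g$value[g$lag_s > 0] / (4 * D * lag) - 1)[1:10]), 0.05)
})

test_that("very stiff traps freeze the tracks and dt <= 0 errors", {
  out <- make_confined_tracks(2, kappa = 1e6, n_frames = 200, seed = 10)
  expect_lt(max(abs(out$tracks$x_um - ave(out$tracks$x_um, out$tracks$id))),
            0.01)
  expect_error(make_confined_tracks(2, dt = 0), "dt")
})

test_that("fractional tracks carry the requested subdiffusion exponent", {
  out <- make_subdiffusive_tracks(60, alpha = 0.5, n_frames = 256,
                                  dt = 0.125, seed = 11)
  g <- g2_msd(out$tracks, com = NULL, max_lag = 64)
  fit <- fit_exponent(g, window = c(0.1, 8))
  expect_lt(abs(fit$alpha - 0.5), 0.06)
})

test_that("blinking removes the right fraction and keeps identity", {
  out <- make_confined_tracks(5, n_frames = 200, seed = 13)
  same <- make_blinking(out$tracks, off_prob = 0)
  expect_identical(nrow(same), nrow(out$tracks))
  bl <- make_blinking(out$tracks, off_prob = 0.5, seed = 14)
  n0 <- nrow(out$tracks)
  expect_lt(abs(nrow(bl) - 0.5 * n0), 3 * sqrt(n0 * 0.25) + 1)
  expect_true(all(bl$id %in% out$tracks$id))
  nearly_all <- make_blinking(out$tracks, off_prob = 0.999, seed = 15)
  expect_lt(nrow(nearly_all), 10)
})
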