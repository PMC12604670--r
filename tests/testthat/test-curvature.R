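test_that("four corner points triangulate into two triangles", {
  pts <- rbind(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(0, 1, 0))
  mesh <- triangulate_points(pts + 1e-6 * matrix(sin(1:12), 4, 3))
  expect_equal(nrow(mesh$triangles), 2)
  expect_error(triangulate_points(cbind(1:5, 2 * (1:5), 0)), "collinear")
})

test_that("hemispherical caps triangulate without fold-overs", {
  set.seed(3)
  n <- 200
  th <- runif(n, 0, 2 * pi); r2 <- sqrt(runif(n, 0, 0.4))
  pts <- cbind(r2 * cos(th), r2 * sin(th), sqrt(1 - r2^2))
  mesh <- triangulate_points(pts)
  ## injective projection: all projected triangles keep positive area
  nrm <- attr(mesh, "normal")
  u <- pts %*% svd(sweep(pts, 2, colMeans(pts)))$v[, 1:2]
  areas <- apply(mesh$triangles, 1, function(tr) {
    a <- u[tr[1], ]; b <- u[tr[2], ]; c <- u[tr[3], ]
    (b[1] - a[1]) * (c[2] - a[2]) - (b[2] - a[2]) * (c[1] - a[1])
  })
  expect_true(all(areas > 0) || all(areas < 0))
})

test_that("mean curvature of a sphere is 1/R at interior vertices", {
  R <- 2
  xs <- seq(-0.55, 0.55, length.out = 17)
  gr <- as.matrix(expand.grid(x = xs, y = xs))
  pts <- cbind(R * gr, R * sqrt(1 - gr[, 1]^2 - gr[, 2]^2))
  mesh <- triangulate_points(pts)
  cv <- mean_curvature(mesh)
  H <- cv$H[cv$interior]
  expect_lt(max(abs(abs(H) - 1 / R) / (1 / R)), 0.03)
  expect_equal(length(unique(sign(H))), 1)   # one consistent sign
})

test_that("flat patches have exactly zero mean curvature", {
  mesh <- grid_mesh(function(x, y) 0 * x, n = 15)
  cv <- mean_curvature(mesh)
  expect_lt(max(abs(cv$H[cv$interior])), 1e-8)
  expect_lt(abs(cv$H_bar), 1e-8)
})

test_that("the saddle z = (x^2 - y^2)/2 has H ~ 0 but K < 0 at the origin", {
  mesh <- grid_mesh(function(x, y) (x^2 - y^2) / 2, n = 21, half = 1)
  cv <- mean_curvature(mesh)
  origin <- which.min(rowSums(mesh$vertices[, 1:2]^2))
  expect_lt(abs(cv$H[origin]), 0.02)
  expect_lt(cv$K[origin], -0.5)   # analytic K = -1 at the origin
})

test_that("reflection through the fit plane negates every curvature", {
  ## same winding (hence same orientation convention), mirrored heights
  mesh <- grid_mesh(function(x, y) 0.3 * exp(-(x^2 + y^2)), n = 15)
  cv <- mean_curvature(mesh)
  flipped <- disk_mesh(mesh$vertices %*% diag(c(1, 1, -1)), mesh$triangles)
  cv2 <- mean_curvature(flipped)
  expect_equal(cv2$H[cv2$interior], -cv$H[cv$interior], tolerance = 1e-10)
})

test_that("sphere curvature error shrinks under mesh refinement", {
  R <- 2
  err <- vapply(c(9, 17, 33), function(n) {
    xs <- seq(-0.55, 0.55, length.out = n)
    gr <- as.matrix(expand.grid(x = xs, y = xs))
    pts <- cbind(R * gr, R * sqrt(1 - gr[, 1]^2 - gr[, 2]^2))
    cv <- mean_curvature(triangulate_points(pts))
    max(abs(abs(cv$H[cv$interior]) - 1 / R))
  }, 1.0)
  expect_true(all(diff(err) < 0))
})

test_that("curvature time series track sign and magnitude per frame", {
  ## static dome: constant positive H-bar when oriented upward
  xs <- seq(-0.7, 0.7, length.out = 13)
  gr <- as.matrix(expand.grid(x = xs, y = xs))
  gr <- gr + matrix(sin(seq_len(nrow(gr) * 2)) * 1e-4, ncol = 2)
  dome <- cbind(2 * gr, 2 * sqrt(1 - gr[, 1]^2 - gr[, 2]^2))
  coms <- array(0, c(3, nrow(dome), 3))
  for (f in 1:3) coms[f, , ] <- dome
  cs <- curvature_timeseries(coms)
  expect_equal(length(unique(round(cs$H_bar, 12))), 1)
  expect_equal(attr(cs, "sign_flips"), 0)
  expect_equal(attr(cs, "mean_abs_H"), abs(cs$H_bar[1]))
  ## mirrored trajectory has the same magnitude with one consistent sign
  coms_m <- coms
  coms_m[, , 3] <- -coms_m[, , 3]
  cs_m <- curvature_timeseries(coms_m)
  expect_equal(abs(cs_m$H_bar), abs(cs$H_bar), tolerance = 1e-8)
  expect_equal(attr(cs_m, "sign_flips"), 0)
})
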