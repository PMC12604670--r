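## Shared fixtures, built in code at test time.

## binary masks as kdna_region objects without going through segmentation
region_from_mask <- function(mask, pixel_size = 1) {
  boundary <- extract_boundary(mask)
  idx <- which(mask, arr.ind = TRUE)
  centroid <- c(x = mean(idx[, 2]) - 1, y = mean(idx[, 1]) - 1)
  r0 <- sqrt(max((boundary[, 1] - centroid[1])^2 +
                 (boundary[, 2] - centroid[2])^2))
  structure(list(mask = mask, boundary = boundary, centroid = centroid,
                 r0 = r0, pixel_size = pixel_size), class = "kdna_region")
}

disk_mask <- function(n = 128, radius = n / 2 - 8) {
  xg <- matrix(0:(n - 1), n, n, byrow = TRUE)
  yg <- matrix(0:(n - 1), n, n)
  c0 <- (n - 1) / 2
  (xg - c0)^2 + (yg - c0)^2 <= radius^2
}

ellipse_mask <- function(n = 128, a = n / 2 - 10, b = n / 3) {
  xg <- matrix(0:(n - 1), n, n, byrow = TRUE)
  yg <- matrix(0:(n - 1), n, n)
  c0 <- (n - 1) / 2
  ((xg - c0) / a)^2 + ((yg - c0) / b)^2 <= 1
}

crescent_mask <- function(n = 128) {
  xg <- matrix(0:(n - 1), n, n, byrow = TRUE)
  yg <- matrix(0:(n - 1), n, n)
  c0 <- (n - 1) / 2
  big <- (xg - c0)^2 + (yg - c0)^2 <= (n / 2 - 10)^2
  hole <- (xg - c0 - n / 6)^2 + (yg - c0)^2 <= (n / 3)^2
  big & !hole
}

## brute-force distance oracle, independent of the packaged kernel
brute_min_dist <- function(xy, boundary) {
  vapply(seq_len(nrow(xy)), function(i) {
    min(sqrt((boundary[, 1] - xy[i, 1])^2 + (boundary[, 2] - xy[i, 2])^2))
  }, 1.0)
}

## single isolated ring as a minimal network (m beads, circle of matching
## circumference), for persistence-length and energy tests
single_ring_network <- function(m = 60, bond = 0.965) {
  R <- m * bond / (2 * pi)
  phi <- seq(0, 2 * pi, length.out = m + 1)[seq_len(m)]
  beads <- cbind(R * cos(phi), R * sin(phi), 0)
  structure(list(rings = list(list(class = "mini", beads = beads)),
                 graph = data.frame(a = integer(0), b = integer(0)),
                 link_edges = data.frame(a = integer(0), b = integer(0),
                                         lk = integer(0)),
                 n_mini = 1L, beads_per_ring = m, spacing = NA,
                 mini_radius = R, boundary_ids = integer(0),
                 mode = "MO", seed = 0), class = "olympic_network")
}

## circle of m points for linking tests
circle3d <- function(m = 60, R = 1, center = c(0, 0, 0), plane = "xy") {
  th <- seq(0, 2 * pi, length.out = m + 1)[seq_len(m)]
  p <- switch(plane,
    xy = cbind(R * cos(th), R * sin(th), 0),
    xz = cbind(R * cos(th), 0, R * sin(th)),
    yz = cbind(0, R * cos(th), R * sin(th)))
  sweep(p, 2, center, "+")
}

## structured height-field mesh z = f(x, y) on a square grid, triangulated
## explicitly (no Delaunay involved)
grid_mesh <- function(f, n = 21, half = 1) {
  xs <- seq(-half, half, length.out = n)
  v <- as.matrix(expand.grid(x = xs, y = xs))
  verts <- cbind(v, z = f(v[, 1], v[, 2]))
  tris <- NULL
  id <- function(i, j) (j - 1) * n + i
  for (j in 1:(n - 1)) for (i in 1:(n - 1)) {
    tris <- rbind(tris,
                  c(id(i, j), id(i + 1, j), id(i + 1, j + 1)),
                  c(id(i, j), id(i + 1, j + 1), id(i, j + 1)))
  }
  disk_mesh(verts, tris)
}
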