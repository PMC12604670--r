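## Discrete mean curvature of the minicircle-COM surface.
##
## The surface through the minicircle centres of mass is triangulated by
## projecting the points onto their best-fit plane and computing the 2D
## Delaunay triangulation there. Mean curvature is the cotangent-Laplacian
## (mean-curvature-normal) estimate with mixed Voronoi vertex areas
## (Meyer et al. discretisation); Gaussian curvature is the angle defect.
## Boundary vertices are excluded from surface averages (the discrete
## operators are unreliable there). The sign convention: curvature is
## positive where the surface bows toward the mesh orientation normal,
## which is tracked for continuity across frames.

#' Construct a triangle mesh with boundary bookkeeping
#'
#' @param vertices n x 3 coordinate matrix.
#' @param triangles k x 3 integer matrix of 1-based vertex indices with
#'   consistent winding.
#' @return A `disk_mesh`: `vertices`, `triangles`, `boundary` (indices of
#'   vertices on an edge incident to exactly one triangle).
#' @export
disk_mesh <- function(vertices, triangles) {
  vertices <- as.matrix(vertices)
  triangles <- as.matrix(triangles)
  stopifnot(ncol(vertices) == 3, ncol(triangles) == 3,
            min(triangles) >= 1, max(triangles) <= nrow(vertices))
  edges <- rbind(triangles[, 1:2], triangles[, 2:3], triangles[, c(3, 1)])
  key <- paste(pmin(edges[, 1], edges[, 2]), pmax(edges[, 1], edges[, 2]))
  cnt <- table(key)
  if (any(cnt > 2)) stop("non-manifold mesh: edge shared by > 2 triangles")
  bedges <- edges[key %in% names(cnt)[cnt == 1], , drop = FALSE]
  structure(list(vertices = vertices, triangles = triangles,
                 boundary = sort(unique(as.vector(bedges)))),
            class = "disk_mesh")
}

#' Triangulate a point cloud as a height-field disk
#'
#' Projects the points onto their best-fit plane (principal components),
#' runs a 2D Delaunay triangulation in that plane, and lifts the triangles
#' back to 3D. Triangle winding is consistent, oriented so the mesh normal
#' has positive dot product with the best-fit plane normal (or with
#' `reference_normal` when given, for frame-to-frame continuity).
#'
#' @param points n x 3 matrix (n >= 4, not collinear).
#' @param reference_normal Optional length-3 vector fixing the orientation.
#' @return A [disk_mesh()] with attribute `normal` (the orienting normal).
#' @export
triangulate_points <- function(points, reference_normal = NULL) {
  points <- as.matrix(points)
  stopifnot(ncol(points) == 3)
  if (nrow(points) < 4) stop("need >= 4 points")
  ctr <- colMeans(points)
  X <- sweep(points, 2, ctr)
  sv <- svd(X)
  if (sv$d[2] < 1e-10 * sv$d[1])
    stop("degenerate point set (collinear): cannot triangulate")
  normal <- sv$v[, 3]
  if (!is.null(reference_normal) && sum(normal * reference_normal) < 0)
    normal <- -normal
  u <- X %*% sv$v[, 1]
  v <- X %*% sv$v[, 2]
  tri <- cpp_delaunay(as.numeric(u), as.numeric(v))
  ## prune boundary slivers: the Delaunay triangulation fills the convex
  ## hull, so ragged point clouds acquire degenerate triangles along the
  ## rim whose cotangent weights would poison nearby vertices; peel
  ## boundary triangles with a tiny minimum angle until none remain
  repeat {
    edges <- rbind(tri[, 1:2], tri[, 2:3], tri[, c(3, 1)])
    key <- paste(pmin(edges[, 1], edges[, 2]), pmax(edges[, 1], edges[, 2]))
    once <- names(table(key))[table(key) == 1]
    tri_keys <- matrix(key, nrow = nrow(tri))
    on_boundary <- rowSums(matrix(tri_keys %in% once, nrow = nrow(tri))) > 0
    min_ang <- apply(tri, 1, function(tr) {
      p <- cbind(u, v)[tr, ]
      a <- sqrt(sum((p[2, ] - p[3, ])^2))
      b <- sqrt(sum((p[1, ] - p[3, ])^2))
      cc <- sqrt(sum((p[1, ] - p[2, ])^2))
      min(acos(pmin(pmax(c((b^2 + cc^2 - a^2) / (2 * b * cc),
                           (a^2 + cc^2 - b^2) / (2 * a * cc),
                           (a^2 + b^2 - cc^2) / (2 * a * b)), -1), 1)))
    })
    drop <- on_boundary & min_ang < (10 * pi / 180)
    if (!any(drop) || sum(!drop) < 1) break
    tri <- tri[!drop, , drop = FALSE]
  }
  ## cpp triangles are CCW in (u, v); make winding agree with `normal`
  e1 <- sv$v[, 1]; e2 <- sv$v[, 2]
  if (sum((pracma_cross(e1, e2)) * normal) < 0) tri <- tri[, c(1, 3, 2)]
  mesh <- disk_mesh(points, tri)
  attr(mesh, "normal") <- normal
  mesh
}

pracma_cross <- function(a, b)
  c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])

#' Discrete mean (and Gaussian) curvature of a mesh
#'
#' Cotangent-Laplacian mean-curvature normal with mixed Voronoi areas:
#' per interior vertex, `H = 0.5 * (L_i . n_i)` where
#' `L_i = sum_j (cot a_ij + cot b_ij)(x_i - x_j) / (2 A_i)` and `n_i` is
#' the angle-weighted vertex normal from the mesh winding. Gaussian
#' curvature is the angle defect over the same area. Zero-area triangles
#' are skipped with a warning.
#'
#' @param mesh A [disk_mesh()] or [triangulate_points()] result.
#' @return A list of class `curvature_frame`: per-vertex `H`, `K`, `area`,
#'   `interior` (logical), and the area-weighted interior averages
#'   `H_bar`, `H_bar_abs` (`= |H_bar|`) and `K_bar`.
#' @export
mean_curvature <- function(mesh) {
  stopifnot(inherits(mesh, "disk_mesh"))
  V <- mesh$vertices; Tm <- mesh$triangles
  n <- nrow(V)
  lap <- matrix(0, n, 3)
  area <- numeric(n)
  angsum <- numeric(n)
  vnorm <- matrix(0, n, 3)
  dropped <- 0L
  for (t in seq_len(nrow(Tm))) {
    id <- Tm[t, ]
    p <- V[id, , drop = FALSE]
    e <- list(p[2, ] - p[1, ], p[3, ] - p[2, ], p[1, ] - p[3, ])
    nrm <- pracma_cross(e[[1]], -e[[3]])
    a2 <- sqrt(sum(nrm^2))             # 2 * triangle area
    if (a2 < 1e-14) { dropped <- dropped + 1L; next }
    ## angles at the three corners
    ang <- numeric(3)
    for (k in 1:3) {
      u <- -e[[c(3, 1, 2)[k]]]; w <- e[[k]]
      ang[k] <- acos(pmin(pmax(sum(u * w) / sqrt(sum(u^2) * sum(w^2)), -1), 1))
    }
    cotg <- 1 / tan(ang)
    ## mixed Voronoi area (Meyer et al.): Voronoi for acute triangles,
    ## half/quarter split at obtuse ones
    l2 <- c(sum(e[[1]]^2), sum(e[[2]]^2), sum(e[[3]]^2)) # opposite 3,1,2
    tri_area <- a2 / 2
    if (all(ang < pi / 2 + 1e-12)) {
      ## corner k gets 1/8 (l_adj1^2 cot(opp1) + l_adj2^2 cot(opp2))
      av <- c((l2[1] * cotg[3] + l2[3] * cotg[2]) / 8,
              (l2[1] * cotg[3] + l2[2] * cotg[1]) / 8,
              (l2[2] * cotg[1] + l2[3] * cotg[2]) / 8)
    } else {
      ob <- which.max(ang)
      av <- rep(tri_area / 4, 3)
      av[ob] <- tri_area / 2
    }
    for (k in 1:3) {
      area[id[k]] <- area[id[k]] + av[k]
      angsum[id[k]] <- angsum[id[k]] + ang[k]
      vnorm[id[k], ] <- vnorm[id[k], ] + (nrm / a2) * ang[k]
    }
    ## cotangent Laplacian contributions: edge (i, j) opposite corner k
    opp <- list(c(1, 2, 3), c(2, 3, 1), c(3, 1, 2)) # edge (a,b), opposite c
    for (k in 1:3) {
      i <- id[opp[[k]][1]]; j <- id[opp[[k]][2]]; c0 <- opp[[k]][3]
      w <- cotg[c0]
      lap[i, ] <- lap[i, ] + w * (V[i, ] - V[j, ])
      lap[j, ] <- lap[j, ] + w * (V[j, ] - V[i, ])
    }
  }
  if (dropped > 0) warning(dropped, " zero-area triangle(s) skipped")
  interior <- !(seq_len(n) %in% mesh$boundary) & area > 0
  H <- rep(NA_real_, n); K <- rep(NA_real_, n)
  nv <- vnorm / pmax(sqrt(rowSums(vnorm^2)), 1e-300)
  Lv <- lap / (2 * pmax(area, 1e-300))
  H[interior] <- 0.5 * rowSums(Lv * nv)[interior]
  K[interior] <- (2 * pi - angsum[interior]) / area[interior]
  w_int <- area[interior]
  H_bar <- sum(H[interior] * w_int) / sum(w_int)
  structure(list(H = H, K = K, area = area, interior = interior,
                 H_bar = H_bar, H_bar_abs = abs(H_bar),
                 K_bar = sum(K[interior] * w_int) / sum(w_int)),
            class = "curvature_frame")
}

#' Mean-curvature time series of a simulated trajectory
#'
#' For each frame, triangulates the minicircle centres of mass, computes
#' the surface-averaged signed mean curvature H-bar, and tracks the mesh
#' orientation normal across frames for sign continuity. Reports the time
#' series of H-bar and |H-bar|, both summary magnitudes (|<H-bar>| and
#' <|H-bar|>) and the number of sign flips.
#'
#' @param x Either an [observables()] result (its `ring_com` is used), a
#'   frame x ring x 3 array of ring COMs, or a trajectory list plus
#'   `network`.
#' @param network Needed when `x` is a trajectory list.
#' @param rings Ring indices to use (default: minicircles when the class
#'   is known, else all).
#' @return A `curvature_summary`: data frame (`frame`, `H_bar`,
#'   `H_bar_abs`) with attributes `abs_mean_H` (= |<H_bar>|),
#'   `mean_abs_H` (= <|H_bar|>), `sign_flips`.
#' @export
curvature_timeseries <- function(x, network = NULL, rings = NULL) {
  if (is.list(x) && !is.null(x$ring_com)) {
    coms <- x$ring_com
    rings <- rings %||% which(x$ring_class == "mini")
  } else if (is.array(x) && length(dim(x)) == 3) {
    coms <- x
    rings <- rings %||% seq_len(dim(x)[2])
  } else {
    stopifnot(!is.null(network))
    obs <- observables(x, network, align = FALSE)
    coms <- obs$ring_com
    rings <- rings %||% which(obs$ring_class == "mini")
  }
  nf <- dim(coms)[1]
  H_bar <- numeric(nf)
  ref_n <- NULL
  for (f in seq_len(nf)) {
    mesh <- triangulate_points(coms[f, rings, ], reference_normal = ref_n)
    ref_n <- attr(mesh, "normal")
    H_bar[f] <- mean_curvature(mesh)$H_bar
  }
  flips <- sum(diff(sign(H_bar[H_bar != 0])) != 0)
  structure(data.frame(frame = seq_len(nf), H_bar = H_bar,
                       H_bar_abs = abs(H_bar)),
            abs_mean_H = abs(mean(H_bar)),
            mean_abs_H = mean(abs(H_bar)),
            sign_flips = flips,
            class = c("curvature_summary", "data.frame"))
}
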