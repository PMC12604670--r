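## Construction of catenated ring-polymer (Olympic) networks.
##
## Minicircle-only (MO) networks are built on a honeycomb patch (the only
## uniform degree-3 planar lattice): each node carries one ring, each
## lattice edge one Hopf link. Rings are realised as "sheared circles" --
## the planar curve x'^2 + y'^2 = R^2 lifted onto the plane z = s * y'
## (sublattice A) or z = s * x' (sublattice B), with the shear sign
## s = +/-1 drawn at random per ring (random link chirality). With
## R = 0.78 d (d the lattice spacing) every lattice edge realises a Hopf
## link and no other pair links; both facts are verified numerically with
## the Gauss linking integral, never assumed.
##
## Maxicircles are added to a slit-compressed disk either through
## uniformly sampled minicircles (linked diffuse, LD) or through the rim
## cycle (linked border, LB), as a serpentine that alternately passes up
## and down through the openings of the chosen minicircles, plus a clasp
## corridor outside the disk where the three maxicircles interlink
## pairwise (|Lk| = 1).

.RING_PERIM_FACTOR <- 7.640396  # arc length of the unit sheared circle

## honeycomb patch of n nodes: positions, sublattice, edges, rim order
.honeycomb_patch <- function(n, d) {
  m <- ceiling(sqrt(n / 2)) + 3
  g <- expand.grid(n1 = -m:m, n2 = -m:m)
  ax <- sqrt(3) * d; a2x <- sqrt(3) / 2 * d; a2y <- 1.5 * d
  base_x <- g$n1 * ax + g$n2 * a2x
  base_y <- g$n2 * a2y
  sites <- rbind(
    data.frame(x = base_x, y = base_y, sub = "A"),
    data.frame(x = base_x, y = base_y + d, sub = "B"))
  ctr <- c(0, d / 2)
  sites$dist <- sqrt((sites$x - ctr[1])^2 + (sites$y - ctr[2])^2)
  sites <- sites[order(sites$dist), ]
  sel <- sites[seq_len(n), ]
  ## adjacency: lattice neighbours are exactly at distance d
  edge_list <- function(s) {
    dx <- outer(s$x, s$x, "-"); dy <- outer(s$y, s$y, "-")
    dd <- sqrt(dx^2 + dy^2)
    idx <- which(abs(dd - d) < 1e-6 * d & upper.tri(dd), arr.ind = TRUE)
    data.frame(a = idx[, 1], b = idx[, 2])
  }
  connected <- function(s, e) {
    if (nrow(s) == 1) return(TRUE)
    adj <- split(c(e$b, e$a), c(e$a, e$b))
    seen <- logical(nrow(s)); seen[1] <- TRUE; queue <- 1L
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      for (w in adj[[as.character(v)]]) if (!seen[w]) {
        seen[w] <- TRUE; queue <- c(queue, w)
      }
    }
    all(seen)
  }
  k <- n
  while (!connected(sel, edge_list(sel)) && k < nrow(sites)) {
    ## grow the candidate pool until the n closest sites are connected
    k <- k + 1
    pool <- sites[seq_len(k), ]
    e <- edge_list(pool)
    adj <- split(c(e$b, e$a), c(e$a, e$b))
    seen <- logical(k); seen[1] <- TRUE; queue <- 1L
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      for (w in adj[[as.character(v)]]) if (!seen[w]) {
        seen[w] <- TRUE; queue <- c(queue, w)
      }
    }
    comp <- which(seen)
    if (length(comp) >= n) {
      sel <- pool[comp[seq_len(n)], ]
      break
    }
  }
  rownames(sel) <- NULL
  edges <- edge_list(sel)
  ## rim: nodes with fewer than 3 patch neighbours, ordered by angle
  deg <- tabulate(c(edges$a, edges$b), nbins = n)
  rim <- which(deg < 3)
  cx <- mean(sel$x); cy <- mean(sel$y)
  rim <- rim[order(atan2(sel$y[rim] - cy, sel$x[rim] - cx))]
  list(sites = sel, edges = edges, rim = rim)
}

## m beads equally spaced in arc length along a sheared circle at `center`
.ring_beads <- function(center, R, m, sub, s) {
  phi <- seq(0, 2 * pi, length.out = 4097)[-4097]
  if (sub == "A") {
    pts <- cbind(R * cos(phi), R * sin(phi), s * R * sin(phi))
  } else {
    pts <- cbind(R * cos(phi), R * sin(phi), s * R * cos(phi))
  }
  seg <- sqrt(rowSums((pts[c(2:nrow(pts), 1), ] - pts)^2))
  cum <- c(0, cumsum(seg))
  total <- cum[length(cum)]
  want <- seq(0, total, length.out = m + 1)[seq_len(m)]
  ii <- findInterval(want, cum, rightmost.closed = TRUE)
  frac <- (want - cum[ii]) / seg[ii]
  nxt <- c(2:nrow(pts), 1)
  out <- pts[ii, ] + frac * (pts[nxt[ii], ] - pts[ii, ])
  sweep(out, 2, c(center[1], center[2], 0), "+")
}

#' Build a minicircle-only (MO) Olympic network
#'
#' Places `n_rings` rings on a roughly disk-shaped honeycomb patch
#' (valence 3 in the interior), realises every lattice edge as a Hopf link
#' with random chirality, and verifies each intended link numerically with
#' the Gauss linking integral.
#'
#' @param n_rings Number of minicircles (>= 2).
#' @param beads_per_ring Beads per minicircle (default 60).
#' @param spacing Lattice spacing in sigma; default chosen so that bead
#'   spacing is ~0.965 sigma and the ring radius is 0.78 x spacing (the
#'   geometric window in which each lattice edge links and no other pair
#'   can).
#' @param seed Integer seed (chirality pattern is reproducible).
#' @param verify If `TRUE` (default), check every lattice edge realises
#'   `|Lk| = 1` and record the realised sign as the edge chirality.
#' @return An `olympic_network`.
#' @export
build_mo <- function(n_rings, beads_per_ring = 60, spacing = NULL, seed = 1,
                     verify = TRUE) {
  stopifnot(n_rings >= 2, beads_per_ring >= 12)
  R <- beads_per_ring * 0.965 / .RING_PERIM_FACTOR
  d <- spacing %||% (R / 0.78)
  if (R <= d / sqrt(2) + 1e-9)
    stop(sprintf("spacing too large to link: ring radius %.3f <= d/sqrt(2) = %.3f; first failing edge would be 1-2", R, d / sqrt(2)))
  if (2 * R >= sqrt(3) * d - 1e-9)
    stop(sprintf("spacing too small: rings of radius %.3f would overlap second neighbours at sqrt(3) d = %.3f", R, sqrt(3) * d))
  patch <- .honeycomb_patch(n_rings, d)
  with_seed(seed, {
    chir <- sample(c(-1, 1), n_rings, replace = TRUE)
    rings <- lapply(seq_len(n_rings), function(i) {
      list(class = "mini",
           beads = .ring_beads(c(patch$sites$x[i], patch$sites$y[i]),
                               R, beads_per_ring, patch$sites$sub[i],
                               chir[i]))
    })
    net <- structure(list(
      rings = rings,
      graph = patch$edges,
      link_edges = data.frame(a = patch$edges$a, b = patch$edges$b,
                              lk = NA_integer_),
      centers = cbind(patch$sites$x, patch$sites$y),
      sublattice = patch$sites$sub,
      chirality = chir,
      boundary_ids = patch$rim,
      spacing = d, mini_radius = R,
      beads_per_ring = beads_per_ring,
      n_mini = n_rings,
      mode = "MO", seed = seed), class = "olympic_network")
    if (verify) {
      for (e in seq_len(nrow(net$link_edges))) {
        lk <- linking_number(rings[[net$link_edges$a[e]]]$beads,
                             rings[[net$link_edges$b[e]]]$beads)
        if (abs(lk) != 1)
          stop(sprintf("construction error: edge %d-%d realises Lk = %d, not a Hopf link",
                       net$link_edges$a[e], net$link_edges$b[e], lk))
        net$link_edges$lk[e] <- lk
      }
    }
    net
  })
}

#' @export
print.olympic_network <- function(x, ...) {
  nmaxi <- sum(vapply(x$rings, function(r) r$class == "maxi", TRUE))
  cat(sprintf("olympic_network (%s): %d minicircles x %d beads%s, %d link edges, spacing %.2f sigma\n",
              x$mode, x$n_mini, x$beads_per_ring,
              if (nmaxi) sprintf(" + %d maxicircles", nmaxi) else "",
              nrow(x$link_edges), x$spacing))
  invisible(x)
}

#' Ring bead counts and stacked bead coordinates of a network
#' @param net An `olympic_network`.
#' @return `ring_lengths`: integer vector of beads per ring;
#'   `net_positions`: one n x 3 matrix of all bead positions, rings
#'   stacked in order.
#' @export
ring_lengths <- function(net)
  vapply(net$rings, function(r) nrow(r$beads), 1L)

#' @rdname ring_lengths
#' @export
net_positions <- function(net)
  do.call(rbind, lapply(net$rings, `[[`, "beads"))

set_positions <- function(net, pos) {
  len <- ring_lengths(net)
  off <- c(0L, cumsum(len))
  for (i in seq_along(net$rings))
    net$rings[[i]]$beads <- pos[(off[i] + 1):off[i + 1], , drop = FALSE]
  net
}

#' Gauss linking number of two closed polylines
#'
#' Exact segment-pair double sum of the Gauss integral, rounded to the
#' nearest integer. Numerically singular configurations (touching
#' segments) are refined by midpoint subdivision and retried; persistent
#' degeneracy or a non-integer result is an error.
#'
#' @param ring_a,ring_b Numeric matrices (n x 3) of bead positions along a
#'   closed ring (last bead connects to first).
#' @param tol Tolerance for integer rounding (default 0.2).
#' @return Integer linking number (antisymmetric under orientation
#'   reversal of either ring).
#' @export
linking_number <- function(ring_a, ring_b, tol = 0.2) {
  ring_a <- as.matrix(ring_a); ring_b <- as.matrix(ring_b)
  stopifnot(ncol(ring_a) == 3, ncol(ring_b) == 3)
  refine <- function(r) {
    mid <- (r + r[c(2:nrow(r), 1), ]) / 2
    out <- matrix(0, 2 * nrow(r), 3)
    out[seq(1, 2 * nrow(r), 2), ] <- r
    out[seq(2, 2 * nrow(r), 2), ] <- mid
    out
  }
  for (attempt in 1:3) {
    res <- cpp_linking_number(ring_a, ring_b)
    if (!res$degenerate && abs(res$lk - round(res$lk)) <= tol)
      return(as.integer(round(res$lk)))
    ring_a <- refine(ring_a); ring_b <- refine(ring_b)
  }
  stop(sprintf("linking number %.4f did not converge to an integer (segments may intersect)", res$lk))
}

#' Full linking matrix of a network
#'
#' Gauss linking number for every ring pair (with a rigorous
#' disjoint-bounding-sphere prefilter for distant pairs).
#'
#' @param net An `olympic_network`, or a list with `pos` and `len`.
#' @param tol Integer-rounding tolerance.
#' @return Symmetric integer matrix with zero diagonal.
#' @export
link_matrix <- function(net, tol = 0.2) {
  if (inherits(net, "olympic_network")) {
    pos <- net_positions(net); len <- ring_lengths(net)
  } else {
    pos <- net$pos; len <- net$len
  }
  cpp_link_matrix(pos, as.integer(len), tol)
}

#' Verify that the realised topology matches the intended link edges
#'
#' @param net An `olympic_network`.
#' @param tol Integer-rounding tolerance for the Gauss integral.
#' @return List with `ok` (logical), `realised` (matrix), `intended`
#'   (matrix), and `mismatches` (data frame of differing pairs).
#' @export
verify_topology <- function(net, tol = 0.2) {
  realised <- link_matrix(net, tol)
  n <- length(net$rings)
  intended <- matrix(0L, n, n)
  le <- net$link_edges
  for (e in seq_len(nrow(le))) {
    v <- if (is.na(le$lk[e])) realised[le$a[e], le$b[e]] else le$lk[e]
    intended[le$a[e], le$b[e]] <- v
    intended[le$b[e], le$a[e]] <- v
  }
  diff_idx <- which(realised != intended & upper.tri(realised), arr.ind = TRUE)
  list(ok = nrow(diff_idx) == 0, realised = realised, intended = intended,
       mismatches = data.frame(a = diff_idx[, 1], b = diff_idx[, 2]))
}
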