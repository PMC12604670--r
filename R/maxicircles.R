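## Slit compression of the minicircle disk and maxicircle threading.

#' Compress a minicircle network into a slit
#'
#' Runs Langevin dynamics between two harmonic walls whose gap ramps
#' linearly from just beyond the current z-extent down to `slit_gap`,
#' then holds, reproducing the condensed disk-like shape of the network.
#' A short push-off phase (pair forces capped at 200 eps/sigma, reduced
#' temperature) first resolves build-time near-contacts without strand
#' crossing. The full linking matrix is verified before and
#' after; any change aborts.
#'
#' @param network An `olympic_network` (typically fresh from [build_mo()]).
#' @param slit_gap Final wall gap in sigma (e.g. 4).
#' @param params Base [sim_params()] (walls and ramp are overridden).
#' @param ramp_steps,hold_steps Steps for the gap ramp and the hold phase.
#' @param seed Integer seed.
#' @return The network with compressed bead positions (`attr` `slit_gap`
#'   records the gap).
#' @export
compress_to_disk <- function(network, slit_gap, params = sim_params(),
                             ramp_steps = 2e5, hold_steps = 5e4, seed = 1) {
  stopifnot(inherits(network, "olympic_network"), slit_gap > 0)
  link_before <- link_matrix(network)
  zext <- 2 * max(abs(net_positions(network)[, 3])) + 2
  ## push-off phase first: capped pair forces at reduced temperature
  ## resolve build-time near-contacts without strand crossing
  soft <- sim_params(K = params$K, R0 = params$R0, eps = params$eps,
                     sigma = params$sigma, kappa_bend = params$kappa_bend,
                     gamma = params$gamma, dt = params$dt,
                     temperature = 0.1 * params$temperature,
                     wall_gap = max(zext, slit_gap), fmax = 200)
  st <- sim_state(network, soft, seed = seed)
  st <- run_langevin(st, soft, 3e4, seed = seed)
  ramp <- sim_params(K = params$K, R0 = params$R0, eps = params$eps,
                     sigma = params$sigma, kappa_bend = params$kappa_bend,
                     gamma = params$gamma, dt = params$dt,
                     temperature = params$temperature,
                     wall_gap = slit_gap, wall_gap_start = max(zext, slit_gap),
                     wall_ramp_steps = ramp_steps)
  st <- run_langevin(st, ramp, ramp_steps + hold_steps, seed = seed + 1L)
  net <- st$network
  link_after <- link_matrix(net)
  if (!identical(link_before, link_after))
    stop("topology change detected during compression; aborting")
  attr(net, "slit_gap") <- slit_gap
  net
}

## closed-polyline helpers -------------------------------------------------

## split long edges so that corner-cutting smoothing moves the curve by a
## bounded (sub-sigma) amount everywhere
.densify_closed <- function(pts, max_len = 1.5) {
  out <- list()
  n <- nrow(pts)
  for (i in seq_len(n)) {
    a <- pts[i, ]; b <- pts[i %% n + 1, ]
    L <- sqrt(sum((b - a)^2))
    k <- max(1L, ceiling(L / max_len))
    for (t in seq_len(k) - 1L) out[[length(out) + 1L]] <- a + (t / k) * (b - a)
  }
  do.call(rbind, out)
}

.chaikin <- function(pts, iterations = 2) {
  for (it in seq_len(iterations)) {
    nxt <- pts[c(2:nrow(pts), 1), , drop = FALSE]
    q <- 0.75 * pts + 0.25 * nxt
    r <- 0.25 * pts + 0.75 * nxt
    out <- matrix(0, 2 * nrow(pts), 3)
    out[seq(1, nrow(out), 2), ] <- q
    out[seq(2, nrow(out), 2), ] <- r
    pts <- out
  }
  pts
}

.resample_closed <- function(pts, m) {
  seg <- sqrt(rowSums((pts[c(2:nrow(pts), 1), , drop = FALSE] - pts)^2))
  keep <- seg > 1e-9
  pts <- pts[keep, , drop = FALSE]
  seg <- seg[keep]
  cum <- c(0, cumsum(seg))
  total <- cum[length(cum)]
  want <- seq(0, total, length.out = m + 1)[seq_len(m)]
  ii <- findInterval(want, cum, rightmost.closed = TRUE)
  ii[ii > nrow(pts)] <- nrow(pts)
  nxt <- c(2:nrow(pts), 1)
  frac <- (want - cum[ii]) / seg[ii]
  pts[ii, , drop = FALSE] + frac * (pts[nxt[ii], , drop = FALSE] -
                                    pts[ii, , drop = FALSE])
}

## Waypoint path for one maxicircle.
##
## Geometry: maxicircle j owns its own pair of serpentine planes at
## z = +/- h_j (h_j = h + 1.6 (j-1)), so hop segments of different
## maxicircles are never coplanar. The closing segment drops to a private
## corridor plane z_j = -(h_max + 3 + 1.6 (j-1)) and follows an arc lane
## of private radius lane_j = r_c + 6 rho + 2 rho j. Pairwise maxi-maxi
## Hopf links are made at clasp stations on the corridor: the owner winds
## one helical turn (radius rho) around a short axis segment, the
## designated threader dips from its lane through that axis. Lanes, planes
## and radii are all distinct, so no two maxicircle paths are coplanar or
## concentric anywhere.

.maxi_path <- function(j, thread_xy, stations, r_c, rho, h, n_maxi,
                       w_own = 1, dir = 1) {
  ## top hop planes ordered upward with j, bottom hop planes ordered the
  ## SAME way (j = n_maxi has both the highest top and the highest
  ## bottom), so any two maxicircles keep one consistent over/under order
  ## at every projection crossing of their hop chords -- their serpentine
  ## parts then contribute zero linking and the only maxi-maxi links are
  ## the deliberate clasps
  h_top <- h + 1.6 * (j - 1)
  h_bot <- h + 1.6 * (n_maxi - j)
  h_max <- h + 1.6 * (n_maxi - 1)
  lane_z <- -(h_max + 3 + 1.6 * (j - 1))
  lane_r <- r_c + 6 * rho + 2 * rho * j
  station_z <- function(o) -(h_max + 3 + 1.6 * (o - 1))
  k <- nrow(thread_xy)
  stopifnot(k %% 2 == 0)
  pts <- list()
  add <- function(p) pts[[length(pts) + 1L]] <<- p
  for (i in seq_len(k)) {
    up <- i %% 2 == 1
    cxy <- thread_xy[i, ]
    if (up) { add(c(cxy, -h_bot)); add(c(cxy, +h_top)) }
    else    { add(c(cxy, +h_top)); add(c(cxy, -h_bot)) }
  }
  ## connector: radially out at z = -h_bot, then down to the corridor lane
  a1 <- atan2(thread_xy[k, 2], thread_xy[k, 1])
  a2 <- atan2(thread_xy[1, 2], thread_xy[1, 1])
  add(c(lane_r * cos(a1), lane_r * sin(a1), -h_bot))
  add(c(lane_r * cos(a1), lane_r * sin(a1), lane_z))
  ## corridor: travel in direction `dir`, visiting this maxicircle'"'"'s two
  ## clasp stations in angular order, with monotone unwrapped angles
  own <- j
  threads_at <- if (j == 1) n_maxi else j - 1
  events <- data.frame(station = c(own, threads_at),
                       role = c("helix", "thread"))
  if (w_own == 0) events <- events[events$role != "helix", , drop = FALSE]
  t_of <- function(psi, t_min) {
    t <- ((psi - a1) * dir) %% (2 * pi)
    while (t < t_min) t <- t + 2 * pi
    t
  }
  events$t <- vapply(events$station,
                     function(o) t_of(stations$psi[o], 0.25), 1.0)
  events <- events[order(events$t), ]
  ## keep the two events ordered and separated
  if (nrow(events) == 2 && events$t[2] < events$t[1] + 0.5)
    events$t[2] <- t_of(stations$psi[events$station[2]], events$t[1] + 0.5)
  lane_pt <- function(t) {
    a <- a1 + dir * t
    c(lane_r * cos(a), lane_r * sin(a), lane_z)
  }
  t_cur <- 0
  arc_to <- function(t_target) {
    while (t_cur < t_target - 1e-9) {
      t_cur <<- min(t_cur + 0.25, t_target)
      add(lane_pt(t_cur))
    }
  }
  for (e in seq_len(nrow(events))) {
    o <- events$station[e]
    psi <- stations$psi[o]
    Q <- c(r_c * cos(psi), r_c * sin(psi), station_z(o))
    t_hat <- dir * c(-sin(psi), cos(psi), 0)
    n1 <- c(cos(psi), sin(psi), 0)
    n2 <- c(0, 0, 1)
    arc_to(events$t[e] - 0.25)
    if (events$role[e] == "thread") {
      add(Q - 2.5 * rho * t_hat)
      add(Q)
      add(Q + 2.5 * rho * t_hat)
    } else {
      ## |w_own| helical turns (handedness = sign) around the station
      ## axis; entry/exit stubs sit on the inward-radial side and below
      ## the clasp plane, so the approach chords never touch the
      ## partner's on-axis run
      turns <- abs(w_own)
      sgn <- sign(w_own)
      add(Q - 2 * rho * t_hat - 1.3 * rho * n1 - 0.8 * rho * n2)
      phis <- seq(0, 2 * pi * turns, length.out = 4 * turns + 1)
      dels <- seq(-0.5, 0.5, length.out = 4 * turns + 1) * rho
      for (i in seq_along(phis))
        add(Q - rho * cos(phis[i]) * n1 + sgn * rho * sin(phis[i]) * n2 +
            dels[i] * t_hat)
      add(Q + 2 * rho * t_hat - 1.3 * rho * n1 - 0.8 * rho * n2)
    }
    t_cur <- events$t[e] + 0.25
    add(lane_pt(t_cur))
  }
  t_end <- t_of(a2, t_cur + 0.25)
  arc_to(t_end)
  ## connector back up to the first threaded ring
  add(c(lane_r * cos(a2), lane_r * sin(a2), -h_bot))
  do.call(rbind, pts)
}

## signed winding number of a closed 2D polygon around point p
.winding2d <- function(poly, p) {
  dx <- poly[, 1] - p[1]
  dy <- poly[, 2] - p[2]
  ang <- atan2(dy, dx)
  dth <- diff(c(ang, ang[1]))
  dth <- (dth + pi) %% (2 * pi) - pi
  round(sum(dth) / (2 * pi))
}

## point inside the opening of a (possibly folded) ring: a vertical line
## through it pierces the ring's projected polygon with winding +/-1 and
## the polygons of all other rings with winding 0 (so the pass threads
## exactly one ring); among such points prefer maximal clearance
.opening_point <- function(beads, others = list()) {
  poly <- beads[, 1:2, drop = FALSE]
  ctr <- colMeans(poly)
  span <- max(sqrt((poly[, 1] - ctr[1])^2 + (poly[, 2] - ctr[2])^2))
  cand <- rbind(ctr,
                as.matrix(expand.grid(
                  x = ctr[1] + seq(-0.7, 0.7, length.out = 9) * span,
                  y = ctr[2] + seq(-0.7, 0.7, length.out = 9) * span)))
  ## prefilter other rings by bounding box overlap with the candidate area
  near <- Filter(function(o) {
    op <- o[, 1:2, drop = FALSE]
    !(max(op[, 1]) < min(cand[, 1]) || min(op[, 1]) > max(cand[, 1]) ||
      max(op[, 2]) < min(cand[, 2]) || min(op[, 2]) > max(cand[, 2]))
  }, others)
  best <- NULL; best_clear <- -Inf
  fallback <- NULL; fallback_clear <- -Inf
  for (i in seq_len(nrow(cand))) {
    p <- as.numeric(cand[i, ])
    if (abs(.winding2d(poly, p)) != 1L) next
    clear <- min(sqrt((poly[, 1] - p[1])^2 + (poly[, 2] - p[2])^2))
    if (clear > fallback_clear) { fallback_clear <- clear; fallback <- p }
    clean <- TRUE
    for (o in near) {
      if (.winding2d(o[, 1:2, drop = FALSE], p) != 0L) { clean <- FALSE; break }
    }
    if (clean && clear > best_clear) { best_clear <- clear; best <- p }
  }
  best %||% fallback %||% as.numeric(ctr)
}

## verification-driven construction of one maxicircle: start with passes
## through the openings of the chosen rings, then repair pass points
## against the realised Gauss linking numbers (re-aim into the opening of
## a ring that failed to thread; push away from a ring threaded
## unintentionally)
.build_maxi <- function(j, pass_xy, stations, r_c, rho, h, n_maxi,
                        w_own = 0, beads = NULL) {
  ## travel the corridor in whichever direction gives the shorter path
  wp1 <- .maxi_path(j, pass_xy, stations, r_c, rho, h, n_maxi,
                    w_own = w_own, dir = 1)
  wp2 <- .maxi_path(j, pass_xy, stations, r_c, rho, h, n_maxi,
                    w_own = w_own, dir = -1)
  plen <- function(w) sum(sqrt(rowSums((w[c(2:nrow(w), 1), ] - w)^2)))
  wp <- if (plen(wp1) <= plen(wp2)) wp1 else wp2
  sm <- .chaikin(.densify_closed(wp), 2)
  L <- sum(sqrt(rowSums((sm[c(2:nrow(sm), 1), ] - sm)^2)))
  m <- beads %||% max(12L, as.integer(round(L / 0.965)))
  if (L / m > 1.2) m <- as.integer(ceiling(L / 0.965))
  .resample_closed(sm, m)
}

.repair_maxi <- function(j, set, cur_c, mini_rings, stations, r_c, rho, h,
                         n_maxi, beads = NULL, max_iter = 6) {
  pass_xy <- t(vapply(set, function(t)
    .opening_point(mini_rings[[t]], mini_rings[-t]), numeric(2)))
  cent2d <- cur_c[, 1:2, drop = FALSE]
  for (iter in seq_len(max_iter)) {
    ring <- .build_maxi(j, pass_xy, stations, r_c, rho, h, n_maxi,
                        w_own = 0, beads = beads)
    ok <- TRUE
    for (t in seq_along(mini_rings)) {
      lk <- tryCatch(linking_number(ring, mini_rings[[t]]),
                     error = function(e) NA_integer_)
      want <- t %in% set
      if (want && (is.na(lk) || abs(lk) != 1L)) {
        i <- which(set == t)
        pass_xy[i, ] <- .opening_point(mini_rings[[t]], mini_rings[-t]) +
          stats::runif(2, -0.6, 0.6)
        ok <- FALSE
      } else if (!want && (is.na(lk) || lk != 0L)) {
        d <- sqrt((pass_xy[, 1] - cent2d[t, 1])^2 +
                  (pass_xy[, 2] - cent2d[t, 2])^2)
        i <- which.min(d)
        u <- pass_xy[i, ] - cent2d[t, ]
        nu <- sqrt(sum(u^2))
        if (nu < 1e-9) { u <- stats::runif(2, -1, 1); nu <- sqrt(sum(u^2)) }
        pass_xy[i, ] <- pass_xy[i, ] + u / nu * 1.2
        ok <- FALSE
      }
    }
    if (ok) return(list(ring = ring, pass_xy = pass_xy))
  }
  NULL
}

#' Add interlinked maxicircles to a compressed minicircle disk
#'
#' Each maxicircle is a closed chain threaded through a chosen set of
#' minicircles -- sampled uniformly over the disk (`mode = "LD"`, linked
#' diffuse) or taken round-robin from the rim cycle (`mode = "LB"`, linked
#' border) -- by a serpentine path that passes alternately up and down
#' through the openings of the chosen rings. The three maxicircles are
#' additionally interlinked pairwise (`|Lk| = 1`) in a clasp corridor
#' outside the disk. Every realised linking number (maxi-mini and
#' maxi-maxi) is verified with the Gauss integral; on failure the
#' construction is retried with a rotated corridor, then errors.
#'
#' @param network A compressed `olympic_network` (see [compress_to_disk()]).
#' @param n_maxi Number of maxicircles (default 3).
#' @param beads Beads per maxicircle; `NULL` (default) chooses the count
#'   from the path length at ~0.965 sigma spacing. A value too small for
#'   the path is increased with a warning.
#' @param mode `"LD"` or `"LB"`.
#' @param n_thread Minicircles threaded per maxicircle (even; default:
#'   LB uses the whole rim round-robin, LD uses `max(4, ~12%` of the
#'   minicircles`)`).
#' @param seed Integer seed.
#' @param max_retries Construction retries before giving up.
#' @return The network with maxicircle rings appended, `link_edges`
#'   extended by the realised maxi-mini and maxi-maxi links, and
#'   `threaded` listing the minicircles threaded by each maxicircle.
#' @export
add_maxicircles <- function(network, n_maxi = 3, beads = NULL,
                            mode = c("LD", "LB"), n_thread = NULL, seed = 1,
                            max_retries = 5) {
  mode <- match.arg(mode)
  stopifnot(inherits(network, "olympic_network"), n_maxi >= 2)
  if (any(vapply(network$rings, function(r) r$class == "maxi", TRUE)))
    stop("network already has maxicircles")
  pos <- net_positions(network)
  n_mini <- network$n_mini
  len <- ring_lengths(network)
  off <- c(0L, cumsum(len))
  cur_c <- t(vapply(seq_len(n_mini), function(r)
    colMeans(pos[(off[r] + 1):off[r + 1], , drop = FALSE]), numeric(3)))
  ctr <- colMeans(cur_c)
  r_max <- max(sqrt((cur_c[, 1] - ctr[1])^2 + (cur_c[, 2] - ctr[2])^2))
  zmax <- max(abs(pos[, 3]))
  h <- 2 * zmax + 3
  rho <- 1.5

  with_seed(seed, {
    ## threading sets
    sets <- if (mode == "LB") {
      rim <- network$boundary_ids
      lapply(seq_len(n_maxi), function(j) {
        s <- rim[seq(j, length(rim), by = n_maxi)]
        if (length(s) %% 2 == 1) s <- s[-length(s)]
        s
      })
    } else {
      k <- n_thread %||% max(4, 2 * floor(0.06 * n_mini))
      if (k %% 2 == 1) k <- k + 1
      if (n_maxi * k > n_mini)
        stop("not enough minicircles for disjoint LD threading sets")
      pool <- sample.int(n_mini, n_maxi * k)
      lapply(seq_len(n_maxi), function(j) {
        s <- pool[((j - 1) * k + 1):(j * k)]
        ## order as a tour by angle around the disk centre
        s[order(atan2(cur_c[s, 2] - ctr[2], cur_c[s, 1] - ctr[1]))]
      })
    }
    if (any(vapply(sets, length, 1L) < 2))
      stop("each maxicircle must thread at least 2 minicircles")

    link_before <- link_matrix(network)
    mini_rings <- lapply(network$rings[seq_len(n_mini)], `[[`, "beads")
    ## choose the clasp-station base angle that minimises the total
    ## corridor length over the three maxicircles (shorter rings, faster
    ## dynamics, fewer chances for accidental crossings)
    pass0 <- lapply(sets, function(st)
      t(vapply(st, function(t) .opening_point(mini_rings[[t]],
                                              mini_rings[-t]), numeric(2))))
    plen <- function(w) sum(sqrt(rowSums((w[c(2:nrow(w), 1), ] - w)^2)))
    psi_cand <- seq(0, 2 * pi, length.out = 9)[-9]
    tot_len <- vapply(psi_cand, function(p0) {
      st0 <- data.frame(psi = p0 + 0.5 * (seq_len(n_maxi) - 1))
      sum(vapply(seq_len(n_maxi), function(j) {
        min(plen(.maxi_path(j, pass0[[j]], st0, r_max + 4, rho, h, n_maxi,
                            dir = 1)),
            plen(.maxi_path(j, pass0[[j]], st0, r_max + 4, rho, h, n_maxi,
                            dir = -1)))
      }, 1.0))
    }, 1.0)
    psi_best <- psi_cand[which.min(tot_len)]
    for (attempt in seq_len(max_retries)) {
      psi0 <- psi_best + 0.7 * (attempt - 1)  # rotate between attempts
      r_c <- r_max + 4 + 0.5 * (attempt - 1)
      stations <- data.frame(psi = psi0 + 0.5 * (seq_len(n_maxi) - 1))
      ## 1. fix the mini-threading pass points with no clasps present
      ok <- TRUE
      reps <- vector("list", n_maxi)
      for (j in seq_len(n_maxi)) {
        reps[[j]] <- .repair_maxi(j, sets[[j]], cur_c, mini_rings, stations,
                                  r_c, rho, h, n_maxi, beads = beads)
        if (is.null(reps[[j]])) {
          message("attempt ", attempt, ": maxicircle ", j,
                  " failed mini-threading repair")
          ok <- FALSE; break
        }
      }
      if (!ok) next
      ## 2. calibrate the clasp winding per station: the serpentine parts
      ## of two maxicircles already realise some base linking number B;
      ## one helical turn at the station adds a unit u = +/-1; wind
      ## w = (target - B)/u turns so the total is exactly +/-1
      pair_of <- function(o) c(o, o %% n_maxi + 1)
      lk_pair <- function(rings, o) {
        pr <- pair_of(o)
        tryCatch(linking_number(rings[[pr[1]]], rings[[pr[2]]]),
                 error = function(e) NA_integer_)
      }
      rings0 <- lapply(reps, `[[`, "ring")
      base <- vapply(seq_len(n_maxi), function(o) lk_pair(rings0, o), 1L)
      rings1 <- lapply(seq_len(n_maxi), function(j)
        .build_maxi(j, reps[[j]]$pass_xy, stations, r_c, rho, h, n_maxi,
                    w_own = 1, beads = beads))
      unit <- vapply(seq_len(n_maxi), function(o) lk_pair(rings1, o), 1L) -
        base
      if (anyNA(base) || any(abs(unit) != 1L)) {
        message("attempt ", attempt, ": clasp calibration failed (base ",
                paste(base, collapse = ","), "; unit ",
                paste(unit, collapse = ","), ")")
        next
      }
      w <- integer(n_maxi)
      for (o in seq_len(n_maxi)) {
        cand_w <- (c(1L, -1L) - base[o]) %/% unit[o]
        w[o] <- cand_w[which.min(abs(cand_w))]
      }
      maxi_rings <- lapply(seq_len(n_maxi), function(j)
        list(class = "maxi",
             beads = .build_maxi(j, reps[[j]]$pass_xy, stations, r_c, rho,
                                 h, n_maxi, w_own = w[j], beads = beads)))
      ## verify all realised linkings
      cand <- network
      for (j in seq_len(n_maxi)) cand$rings[[n_mini + j]] <- maxi_rings[[j]]
      lm_new <- tryCatch(link_matrix(cand), error = function(e) {
        message("attempt ", attempt, ": ", conditionMessage(e)); NULL })
      if (is.null(lm_new)) { ok <- FALSE; next }
      if (!identical(lm_new[seq_len(n_mini), seq_len(n_mini)], link_before)) {
        message("attempt ", attempt, ": mini-mini block changed")
        ok <- FALSE; next
      }
      new_edges <- list()
      for (j in seq_len(n_maxi)) {
        row <- lm_new[n_mini + j, seq_len(n_mini)]
        want <- rep(0L, n_mini); want[sets[[j]]] <- abs(row[sets[[j]]])
        if (!all(abs(row[sets[[j]]]) == 1L) ||
            !all(row[setdiff(seq_len(n_mini), sets[[j]])] == 0L)) {
          message("attempt ", attempt, ": maxi ", j,
                  " mini links wrong after assembly")
          ok <- FALSE; break
        }
        for (t in sets[[j]])
          new_edges[[length(new_edges) + 1]] <-
            data.frame(a = t, b = n_mini + j, lk = row[t])
      }
      if (ok) {
        for (j1 in seq_len(n_maxi - 1)) for (j2 in (j1 + 1):n_maxi) {
          v <- lm_new[n_mini + j1, n_mini + j2]
          if (abs(v) != 1L) {
            message("attempt ", attempt, ": maxi-maxi (", j1, ",", j2,
                    ") Lk = ", v)
            ok <- FALSE; break
          }
          new_edges[[length(new_edges) + 1]] <-
            data.frame(a = n_mini + j1, b = n_mini + j2, lk = v)
        }
      }
      if (ok) {
        cand$link_edges <- rbind(network$link_edges,
                                 do.call(rbind, new_edges))
        cand$mode <- mode
        cand$threaded <- sets
        attr(cand, "slit_gap") <- attr(network, "slit_gap")
        return(cand)
      }
    }
    stop("maxicircle construction failed linking checks after ",
         max_retries, " retries")
  })
}
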