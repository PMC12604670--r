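## Trajectory reconstruction and lag-time statistics.
##
## g2(t) is the MSD of a tracked particle in the frame of reference of the
## structure's centre of mass:
##   g2(t) = < [ (r_i(t+t0) - r_CM(t+t0)) - (r_i(t0) - r_CM(t0)) ]^2 >,
## averaged over all initial times t0 (overlapping windows) and particles.
## dMSD(t) is the MSD of the pair-distance vector d_ij = r_i - r_j,
## averaged over t0 and pairs; it needs no COM because rigid-body motion
## cancels in the difference.

#' Link per-frame spot detections into trajectories
#'
#' Greedy nearest-neighbour frame-to-frame assignment with gap closing:
#' candidate links are sorted by distance and accepted while both ends are
#' unassigned, links longer than `max_disp` (per frame of gap) are
#' forbidden, and a track missing from up to `memory` consecutive frames
#' can be resumed.
#'
#' @param spots Data frame with columns `frame` and `x_um`, `y_um` (or
#'   `x_px`, `y_px`; the first pair found is used).
#' @param max_disp Maximum displacement per frame, same units as the
#'   coordinates.
#' @param memory Maximum number of consecutive missed frames bridged.
#' @param frame_interval Seconds per frame for the returned track set.
#' @return A [track_set()].
#' @export
link_spots <- function(spots, max_disp, memory = 3, frame_interval = 1 / 8) {
  stopifnot(is.data.frame(spots), "frame" %in% names(spots), max_disp > 0)
  cols <- if (all(c("x_um", "y_um") %in% names(spots))) c("x_um", "y_um")
          else c("x_px", "y_px")
  if (length(unique(spots$frame)) < 2) stop("need spots in >= 2 frames")
  sp <- data.frame(frame = spots$frame, x = spots[[cols[1]]],
                   y = spots[[cols[2]]])
  sp <- sp[order(sp$frame), ]
  last_x <- numeric(0); last_y <- numeric(0); last_f <- integer(0)
  out_id <- integer(nrow(sp)); next_id <- 1L
  row_of <- integer(0)  # row index in sp of each track's last detection
  for (f in unique(sp$frame)) {
    rows <- which(sp$frame == f)
    cand <- which(f - last_f <= memory + 1L & f > last_f)
    assigned_det <- rep(FALSE, length(rows))
    assigned_trk <- rep(FALSE, length(last_f))
    if (length(cand) > 0 && length(rows) > 0) {
      gap <- f - last_f[cand]
      dmat <- sqrt(outer(sp$x[rows], last_x[cand], "-")^2 +
                   outer(sp$y[rows], last_y[cand], "-")^2)
      lim <- matrix(max_disp * gap, nrow = length(rows),
                    ncol = length(cand), byrow = TRUE)
      ok <- which(dmat <= lim, arr.ind = TRUE)
      if (nrow(ok) > 0) {
        ord <- order(dmat[ok])
        for (k in ord) {
          i <- ok[k, 1]; j <- cand[ok[k, 2]]
          if (!assigned_det[i] && !assigned_trk[j]) {
            assigned_det[i] <- TRUE; assigned_trk[j] <- TRUE
            out_id[rows[i]] <- out_id[row_of[j]]
            row_of[j] <- rows[i]
            last_x[j] <- sp$x[rows[i]]; last_y[j] <- sp$y[rows[i]]
            last_f[j] <- f
          }
        }
      }
    }
    for (i in which(!assigned_det)) {
      out_id[rows[i]] <- next_id
      last_x <- c(last_x, sp$x[rows[i]]); last_y <- c(last_y, sp$y[rows[i]])
      last_f <- c(last_f, f); row_of <- c(row_of, rows[i])
      next_id <- next_id + 1L
    }
  }
  df <- data.frame(id = out_id, frame = sp$frame, x_um = sp$x, y_um = sp$y)
  track_set(df, frame_interval = frame_interval)
}

#' Track the structure's centre of mass from the DNA channel
#'
#' Segments each DNA-channel frame and returns the per-frame centroid in
#' micrometres. Frames where segmentation fails are interpolated from
#' neighbouring frames, with a warning.
#'
#' @param movie A `labelled_movie` (uses its `dna` array and calibration)
#'   or a 3D array `c(ny, nx, n_frames)`.
#' @param blur_sigma,threshold_method Passed to [segment_region()].
#' @param pixel_size Micrometres per pixel (taken from the movie if given).
#' @return Data frame `frame`, `x_um`, `y_um`.
#' @export
track_com <- function(movie, blur_sigma = 2, threshold_method = "otsu",
                      pixel_size = NULL) {
  if (inherits(movie, "labelled_movie")) {
    arr <- movie$dna
    pixel_size <- pixel_size %||% movie$pixel_size
  } else {
    arr <- movie
    pixel_size <- pixel_size %||% 1
  }
  if (length(dim(arr)) == 2) arr <- array(arr, dim = c(dim(arr), 1))
  nf <- dim(arr)[3]
  xy <- matrix(NA_real_, nf, 2)
  for (f in seq_len(nf)) {
    reg <- tryCatch(segment_region(arr[, , f], blur_sigma, threshold_method),
                    error = function(e) NULL)
    if (!is.null(reg)) xy[f, ] <- reg$centroid
  }
  if (anyNA(xy[, 1])) {
    if (all(is.na(xy[, 1]))) stop("no frame could be segmented")
    warning(sum(is.na(xy[, 1])), " frame(s) unsegmentable; centroid interpolated")
    for (k in 1:2)
      xy[, k] <- stats::approx(which(!is.na(xy[, k])), xy[!is.na(xy[, k]), k],
                               xout = seq_len(nf), rule = 2)$y
  }
  data.frame(frame = 0:(nf - 1), x_um = xy[, 1] * pixel_size,
             y_um = xy[, 2] * pixel_size)
}

## per-lag sums of squared displacements of a (possibly gappy) 2D series;
## frames must be 0-based integers
.msd_sums <- function(frames, x, y, max_lag) {
  n <- max(frames) + 1L
  xf <- rep(NA_real_, n); yf <- rep(NA_real_, n)
  xf[frames + 1L] <- x; yf[frames + 1L] <- y
  ss <- numeric(max_lag); cnt <- integer(max_lag)
  for (L in seq_len(min(max_lag, n - 1L))) {
    dx <- xf[(1L + L):n] - xf[1:(n - L)]
    dy <- yf[(1L + L):n] - yf[1:(n - L)]
    v <- dx * dx + dy * dy
    ok <- !is.na(v)
    cnt[L] <- sum(ok)
    ss[L] <- sum(v[ok])
  }
  list(ss = ss, cnt = cnt)
}

.msd_curve <- function(lag_s, value, n, kind) {
  keep <- n > 0
  out <- data.frame(lag_s = c(0, lag_s[keep]), value = c(0, value[keep]),
                    n = c(max(n, 0L)[1], n[keep]))
  structure(out, kind = kind, class = c("msd_curve", "data.frame"))
}

#' Centre-of-mass-frame MSD, g2(t)
#'
#' @param tracks A [track_set()].
#' @param com COM trajectory (`frame`, `x_um`, `y_um`); default the track
#'   set's own `com` attribute, or a static origin if absent.
#' @param max_lag Largest lag in frames (default: 1/2 of the frame span,
#'   where the overlapping-window average is still well sampled).
#' @return An `msd_curve` data frame (`lag_s`, `value` in um^2, `n`
#'   displacement pairs per lag), kind `"g2"`; the lag-0 value is exactly 0.
#' @export
g2_msd <- function(tracks, com = NULL, max_lag = NULL) {
  stopifnot(inherits(tracks, "track_set"))
  com <- com %||% attr(tracks, "com")
  dt <- attr(tracks, "frame_interval")
  span <- max(tracks$frame) - min(tracks$frame)
  max_lag <- as.integer(max_lag %||% max(1, span %/% 2))
  if (!is.null(com)) {
    cx <- rep(NA_real_, max(com$frame) + 1L); cy <- cx
    cx[com$frame + 1L] <- com$x_um; cy[com$frame + 1L] <- com$y_um
    if (anyNA(cx[tracks$frame + 1L]))
      stop("COM trajectory must cover every frame used by the tracks")
  }
  ss <- numeric(max_lag); cnt <- integer(max_lag)
  for (id in unique(tracks$id)) {
    tr <- tracks[tracks$id == id, ]
    x <- tr$x_um; y <- tr$y_um
    if (!is.null(com)) {
      x <- x - cx[tr$frame + 1L]
      y <- y - cy[tr$frame + 1L]
    }
    m <- .msd_sums(tr$frame - min(tracks$frame), x, y, max_lag)
    ss <- ss + m$ss; cnt <- cnt + m$cnt
  }
  .msd_curve((1:max_lag) * dt, ifelse(cnt > 0, ss / cnt, NA), cnt, "g2")
}

#' Pair-distance MSD (dMSD) and pair-distance statistics
#'
#' For every pair of concurrently observed tracks, forms the distance
#' vector `d_ij(t) = r_i(t) - r_j(t)` and averages the squared change of
#' that vector over initial times and pairs. Per-pair mean distance and its
#' standard deviation are returned alongside; with `normalise = TRUE` each
#' pair's curve is divided by its squared mean distance before pooling.
#'
#' @param tracks A [track_set()] with >= 2 tracks.
#' @param normalise Divide each pair's curve by its `mean_d^2`.
#' @param max_lag Largest lag in frames (default half the frame span).
#' @return List with `curve` (an `msd_curve`, kind `"dMSD"` or
#'   `"dMSD_normalised"`) and `pairs` (data frame `i`, `j`, `mean_d`,
#'   `sd_d`, `n_frames`).
#' @export
dmsd <- function(tracks, normalise = FALSE, max_lag = NULL) {
  stopifnot(inherits(tracks, "track_set"))
  ids <- unique(tracks$id)
  if (length(ids) < 2) stop("need >= 2 concurrent tracks")
  dt <- attr(tracks, "frame_interval")
  span <- max(tracks$frame) - min(tracks$frame)
  max_lag <- as.integer(max_lag %||% max(1, span %/% 2))
  ss <- numeric(max_lag); cnt <- integer(max_lag)
  pairs <- list()
  per_track <- split(tracks[, c("frame", "x_um", "y_um")], tracks$id)
  per_track <- per_track[as.character(ids)]
  for (a in seq_along(ids)) for (b in seq_len(a - 1L)) {
    ta <- per_track[[a]]; tb <- per_track[[b]]
    common <- intersect(ta$frame, tb$frame)
    if (length(common) < 2) next
    ia <- match(common, ta$frame); ib <- match(common, tb$frame)
    dx <- ta$x_um[ia] - tb$x_um[ib]
    dy <- ta$y_um[ia] - tb$y_um[ib]
    dabs <- sqrt(dx^2 + dy^2)
    m <- .msd_sums(common - min(common), dx, dy, max_lag)
    w <- if (normalise) mean(dabs)^2 else 1
    ss <- ss + m$ss / w; cnt <- cnt + m$cnt
    pairs[[length(pairs) + 1L]] <-
      data.frame(i = ids[b], j = ids[a], mean_d = mean(dabs),
                 sd_d = stats::sd(dabs), n_frames = length(common))
  }
  if (length(pairs) == 0) stop("no pair of tracks shares >= 2 frames")
  kind <- if (normalise) "dMSD_normalised" else "dMSD"
  list(curve = .msd_curve((1:max_lag) * dt,
                          ifelse(cnt > 0, ss / cnt, NA), cnt, kind),
       pairs = do.call(rbind, pairs))
}

#' Fit a power-law exponent on a log-log window of an MSD curve
#'
#' @param curve An `msd_curve`.
#' @param window `c(t_min, t_max)` in seconds; the fit uses lags within the
#'   closed window (>= 4 required, all values > 0).
#' @return An `exponent_fit`: list with `alpha`, `se`, `r2`, `window`,
#'   `n_points`, `prefactor` (value at t = 1 s implied by the fit).
#' @export
fit_exponent <- function(curve, window = NULL) {
  stopifnot(inherits(curve, "msd_curve"))
  d <- curve[curve$lag_s > 0, ]
  window <- window %||% range(d$lag_s)
  d <- d[d$lag_s >= window[1] & d$lag_s <= window[2] & !is.na(d$value), ]
  if (nrow(d) < 4) stop("need >= 4 lag points in the fit window")
  if (any(d$value <= 0)) stop("nonpositive MSD values in the fit window")
  fit <- stats::lm(log10(value) ~ log10(lag_s), data = d)
  ## exact power-law inputs trigger the harmless "essentially perfect
  ## fit" warning from summary.lm; the SE is simply ~0 then
  sm <- suppressWarnings(summary(fit))
  structure(list(alpha = unname(stats::coef(fit)[2]),
                 se = sm$coefficients[2, 2],
                 r2 = sm$r.squared,
                 prefactor = 10^unname(stats::coef(fit)[1]),
                 window = window, n_points = nrow(d)),
            class = "exponent_fit")
}

#' @export
print.exponent_fit <- function(x, ...) {
  cat(sprintf("MSD exponent alpha = %.3f +/- %.3f (R2 = %.3f, %d lags in [%g, %g] s)\n",
              x$alpha, x$se, x$r2, x$n_points, x$window[1], x$window[2]))
  invisible(x)
}

#' Long-time plateau of an MSD curve
#'
#' Mean of the curve beyond `t_min`, with a reliability guard: if the
#' log-log slope beyond `t_min` exceeds `slope_max` the curve is still
#' rising (e.g. free diffusion) and the plateau is flagged unreliable.
#'
#' @param curve An `msd_curve`.
#' @param t_min Plateau onset in seconds (default 10 s).
#' @param slope_max Maximum log-log slope tolerated in the window.
#' @return List `value` (um^2), `se`, `n_lags`, `slope`, `reliable`.
#' @export
msd_plateau <- function(curve, t_min = 10, slope_max = 0.1) {
  stopifnot(inherits(curve, "msd_curve"))
  d <- curve[curve$lag_s > t_min & !is.na(curve$value), ]
  if (nrow(d) < 3) stop("fewer than 3 lags beyond t_min")
  slope <- if (all(d$value > 0))
    unname(stats::coef(stats::lm(log10(value) ~ log10(lag_s), data = d))[2])
  else NA_real_
  reliable <- !is.na(slope) && abs(slope) <= slope_max
  if (!reliable)
    warning(sprintf("plateau unreliable: log-log slope %.3f beyond t_min", slope))
  list(value = mean(d$value), se = stats::sd(d$value) / sqrt(nrow(d)),
       n_lags = nrow(d), slope = slope, reliable = reliable)
}
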