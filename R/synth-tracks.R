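## Synthetic quantum-dot trajectories with closed-form targets.
##
## Confined motion is modelled as overdamped Ornstein-Uhlenbeck dynamics in
## a harmonic trap: per-axis stationary variance kBT/kappa, relaxation time
## gamma/kappa, so the COM-frame MSD plateaus at 4 kBT/kappa in 2D.
## Subdiffusive motion (MSD ~ t^alpha, alpha < 1) is generated as
## fractional Brownian motion with Hurst exponent alpha/2 via the
## Davies-Harte circulant embedding.

#' Construct a track set
#'
#' @param df Data frame with columns `id`, `frame`, `x_um`, `y_um`.
#' @param frame_interval Seconds per frame.
#' @param com Optional data frame (`frame`, `x_um`, `y_um`) with the
#'   structure's centre-of-mass trajectory.
#' @return A `track_set` data frame.
#' @export
track_set <- function(df, frame_interval, com = NULL) {
  stopifnot(all(c("id", "frame", "x_um", "y_um") %in% names(df)),
            frame_interval > 0)
  df <- df[order(df$id, df$frame), ]
  if (any(unlist(tapply(df$frame, df$id, function(f) diff(f) <= 0))))
    stop("frames must be strictly increasing within a track")
  structure(df, frame_interval = frame_interval, com = com,
            class = c("track_set", "data.frame"))
}

#' @export
print.track_set <- function(x, ...) {
  cat("track_set:", length(unique(x$id)), "tracks,", nrow(x), "localisations,",
      "dt =", attr(x, "frame_interval"), "s",
      if (!is.null(attr(x, "com"))) "(with COM trajectory)" else "", "\n")
  invisible(x)
}

#' Generate confined (trapped) 2D quantum-dot tracks
#'
#' Each emitter performs independent overdamped Ornstein-Uhlenbeck motion
#' around its own anchor point: per-axis stationary variance `kBT/kappa`,
#' autocorrelation time `gamma/kappa`. With `kappa = 0` the motion is free
#' Brownian diffusion with `D = kBT/gamma` (2D MSD `4 D t`). An optional
#' common linear drift moves all emitters (and the returned COM) rigidly,
#' and is removable by COM subtraction.
#'
#' @param n_qd Number of emitters.
#' @param kappa Trap stiffness per axis in pN/um (0 for free diffusion).
#' @param temperature Kelvin.
#' @param n_frames Frames per track (>= 100).
#' @param dt Frame interval in seconds.
#' @param gamma Drag coefficient in pN s/um (sets the relaxation time
#'   `gamma/kappa`; default 0.1 gives 2.5 s at the kappa ~ 0.04 pN/um
#'   scale of soft DNA networks).
#' @param anchor_spread Anchors drawn uniformly in a disk of this radius
#'   (um) around the origin.
#' @param drift Length-2 numeric, common drift velocity in um/s.
#' @param seed Integer seed.
#' @return List with `tracks` (a [track_set()] whose `com` attribute holds
#'   the common-frame trajectory) and `truth` (kappa, gamma, temperature,
#'   anchors, per-axis stationary SD).
#' @export
make_confined_tracks <- function(n_qd, kappa = 0.04, temperature = 298,
                                 n_frames = 500, dt = 0.125, gamma = 0.1,
                                 anchor_spread = 1, drift = c(0, 0),
                                 seed = 1) {
  stopifnot(n_qd >= 1, kappa >= 0, n_frames >= 100)
  if (dt <= 0) stop("dt must be > 0")
  kT <- kBT_pN_um(temperature)
  with_seed(seed, {
    th <- stats::runif(n_qd, 0, 2 * pi)
    rad <- anchor_spread * sqrt(stats::runif(n_qd))
    anchors <- cbind(x = rad * cos(th), y = rad * sin(th))
    t_s <- (0:(n_frames - 1)) * dt
    com_path <- cbind(drift[1] * t_s, drift[2] * t_s)
    one_axis <- function() {
      if (kappa > 0) {
        sd_st <- sqrt(kT / kappa)
        rho <- exp(-(kappa / gamma) * dt)
        x <- numeric(n_frames)
        x[1] <- stats::rnorm(1, 0, sd_st)
        innov <- stats::rnorm(n_frames - 1, 0, sd_st * sqrt(1 - rho^2))
        for (i in 2:n_frames) x[i] <- rho * x[i - 1] + innov[i - 1]
        x
      } else {
        D <- kT / gamma
        cumsum(c(0, stats::rnorm(n_frames - 1, 0, sqrt(2 * D * dt))))
      }
    }
    dfs <- lapply(seq_len(n_qd), function(i) {
      data.frame(id = i, frame = 0:(n_frames - 1),
                 x_um = anchors[i, 1] + one_axis() + com_path[, 1],
                 y_um = anchors[i, 2] + one_axis() + com_path[, 2])
    })
    com <- data.frame(frame = 0:(n_frames - 1),
                      x_um = com_path[, 1], y_um = com_path[, 2])
    tr <- track_set(do.call(rbind, dfs), frame_interval = dt, com = com)
    truth <- structure(list(kappa_true = kappa, gamma = gamma,
                            temperature = temperature, alpha_true = 1,
                            sd_stationary = if (kappa > 0) sqrt(kT / kappa) else NA,
                            anchors = anchors, seed = seed),
                       class = "ground_truth")
    list(tracks = tr, truth = truth)
  })
}

#' Generate subdiffusive 2D tracks by fractional Brownian motion
#'
#' Per-axis displacements are fractional Gaussian noise with Hurst
#' exponent `alpha/2`, so the ensemble 2D MSD is `msd1 * t^alpha` with
#' `msd1` the 2D MSD at t = 1 s.
#'
#' @param n_tracks Number of tracks.
#' @param alpha Subdiffusion exponent in (0, 1].
#' @param n_frames Frames per track.
#' @param dt Frame interval (s).
#' @param msd1 Target 2D MSD at 1 s lag, in um^2.
#' @param seed Integer seed.
#' @return List with `tracks` ([track_set()]) and `truth`
#'   (`alpha_true`, `msd1`).
#' @export
make_subdiffusive_tracks <- function(n_tracks, alpha = 0.25, n_frames = 256,
                                     dt = 0.125, msd1 = 0.02, seed = 1) {
  stopifnot(n_tracks >= 1, alpha > 0, alpha <= 1, n_frames >= 8)
  H <- alpha / 2
  sig2 <- (msd1 / 2) * dt^alpha  # per-axis increment variance per frame step
  with_seed(seed, {
    dfs <- lapply(seq_len(n_tracks), function(i) {
      x <- cumsum(c(0, .fgn_davies_harte(n_frames - 1, H, sig2)))
      y <- cumsum(c(0, .fgn_davies_harte(n_frames - 1, H, sig2)))
      data.frame(id = i, frame = 0:(n_frames - 1), x_um = x, y_um = y)
    })
    tr <- track_set(do.call(rbind, dfs), frame_interval = dt)
    truth <- structure(list(alpha_true = alpha, msd1 = msd1, seed = seed),
                       class = "ground_truth")
    list(tracks = tr, truth = truth)
  })
}

## Davies-Harte exact circulant-embedding sampler of fractional Gaussian
## noise: n values with autocovariance
## r(k) = sig2/2 (|k+1|^2H - 2|k|^2H + |k-1|^2H).
.fgn_davies_harte <- function(n, H, sig2 = 1) {
  stopifnot(n >= 1, H > 0, H < 1)
  if (n == 1) return(stats::rnorm(1, 0, sqrt(sig2)))
  k <- 0:n
  r <- sig2 / 2 * (abs(k + 1)^(2 * H) - 2 * abs(k)^(2 * H) + abs(k - 1)^(2 * H))
  circ <- c(r, r[n:2])                  # length 2n first row of circulant
  lam <- Re(stats::fft(circ))
  if (min(lam) < -1e-8 * max(lam))
    stop("circulant embedding failed (negative eigenvalue)")
  lam[lam < 0] <- 0
  M <- 2 * n
  W <- complex(length.out = M)
  W[1] <- stats::rnorm(1)
  W[n + 1] <- stats::rnorm(1)
  re <- stats::rnorm(n - 1); im <- stats::rnorm(n - 1)
  W[2:n] <- complex(real = re, imaginary = im) / sqrt(2)
  W[M:(n + 2)] <- Conj(W[2:n])
  x <- Re(stats::fft(sqrt(lam) * W)) / sqrt(M)
  x[1:n]
}

#' Apply quantum-dot blinking to a spot table or track set
#'
#' Removes each localisation independently with probability `off_prob`,
#' keeping track identity, which stresses gap closing in the linker.
#'
#' @param x A `spot_table` or [track_set()].
#' @param off_prob Per-frame off probability in `[0, 1)`.
#' @param seed Integer seed.
#' @return Object of the same class with rows removed.
#' @export
make_blinking <- function(x, off_prob, seed = NULL) {
  stopifnot(is.data.frame(x), off_prob >= 0, off_prob < 1)
  if (off_prob == 0) return(x)
  with_seed(seed, {
    keep <- stats::runif(nrow(x)) >= off_prob
    out <- x[keep, , drop = FALSE]
    attributes(out)[c("frame_interval", "com")] <-
      attributes(x)[c("frame_interval", "com")]
    class(out) <- class(x)
    out
  })
}
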