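## Synthetic two-channel kDNA movies with known ground truth.
##
## The DNA channel emulates a YOYO-stained kinetoplast: a smooth elliptical
## blob ~4 um across with a brighter annular rim. The QD channel contains a
## handful of point emitters placed by a controllable radial law, convolved
## with a Gaussian PSF and (optionally) corrupted by Poisson-like noise.
## Defaults mirror the acquisition conditions the analyses assume:
## 70 nm pixels, 8 fps.

#' Radial placement law for synthetic emitters
#'
#' @param type `"uniform"` (uniform over the DNA mask, i.e. the
#'   random-deposition null), `"peripheral"` (probability `p_outer` of
#'   falling in the rim shell `r/r0 <= shell_fraction`, uniform within each
#'   stratum), or `"central"` (uniform over `r/r0 >= 0.5`).
#' @param p_outer,shell_fraction Parameters of the peripheral law.
#' @return A `radial_law` list.
#' @export
radial_law <- function(type = c("uniform", "peripheral", "central"),
                       p_outer = 1, shell_fraction = 0.1) {
  type <- match.arg(type)
  stopifnot(p_outer >= 0, p_outer <= 1,
            shell_fraction > 0, shell_fraction < 1)
  structure(list(type = type, p_outer = p_outer,
                 shell_fraction = shell_fraction), class = "radial_law")
}

#' Generate a synthetic two-channel kDNA movie
#'
#' @param n_emitters Number of QD emitters (typically 5-30).
#' @param law A [radial_law()] controlling radial emitter placement.
#' @param shape `c(ny, nx)` frame size in pixels.
#' @param n_frames Number of frames (emitters are static; use the track
#'   generators for dynamics).
#' @param pixel_size Micrometres per pixel (default 0.07).
#' @param frame_interval Seconds between frames (default 1/8, i.e. 8 fps).
#' @param diameter_um DNA structure diameter in micrometres (default 4).
#' @param axis_ratio Minor/major axis ratio of the ellipse.
#' @param rim_boost Relative brightness boost of the annular rim.
#' @param psf_sigma Gaussian PSF sigma in pixels.
#' @param dna_peak,qd_peak Peak photon counts for the two channels.
#' @param background Background photon level added before shot noise.
#' @param noise If `TRUE`, apply Poisson shot noise to both channels; if
#'   `FALSE` the channels are the noiseless expectations (and a movie with
#'   zero emitters has an identically zero QD channel).
#' @param seed Integer seed; generation is reproducible given
#'   (parameters, seed).
#' @return List with `movie` (a `labelled_movie`: `dna`, `qd` arrays of dim
#'   `c(ny, nx, n_frames)`, `pixel_size`, `frame_interval`) and `truth`
#'   (a `ground_truth`: emitter positions in pixels and um, their true
#'   `r/r0`, the law and seed, plus the noiseless mask and its region).
#' @export
make_kdna_image <- function(n_emitters, law = radial_law("uniform"),
                            shape = c(160, 160), n_frames = 1,
                            pixel_size = 0.07, frame_interval = 1 / 8,
                            diameter_um = 4, axis_ratio = 0.9,
                            rim_boost = 0.6, psf_sigma = 1.5,
                            dna_peak = 200, qd_peak = 800, background = 5,
                            noise = TRUE, seed = 1) {
  stopifnot(n_emitters >= 0, inherits(law, "radial_law"), n_frames >= 1)
  ny <- shape[1]; nx <- shape[2]
  a <- diameter_um / 2 / pixel_size          # semi-major axis, px
  b <- a * axis_ratio
  cx <- (nx - 1) / 2; cy <- (ny - 1) / 2
  if (a + 5 > nx / 2 || b + 5 > ny / 2)
    stop("region larger than frame: need >= 5 px margin around the ",
         "structure; enlarge `shape` or shrink `diameter_um`")
  xg <- matrix(0:(nx - 1), ny, nx, byrow = TRUE)
  yg <- matrix(0:(ny - 1), ny, nx)
  e <- sqrt(((xg - cx) / a)^2 + ((yg - cy) / b)^2)
  mask <- e <= 1
  ## smooth interior + brighter rim near e ~ 0.92
  dna0 <- ifelse(mask, (1 - e^4) + rim_boost * exp(-((e - 0.92) / 0.07)^2), 0)
  dna0 <- dna0 / max(dna0) * dna_peak

  ## true r/r0 per mask pixel, from the noiseless mask geometry
  boundary <- extract_boundary(mask)
  region <- structure(list(
    mask = mask, boundary = boundary,
    centroid = c(x = cx, y = cy),
    r0 = sqrt(max((boundary[, 1] - cx)^2 + (boundary[, 2] - cy)^2)),
    pixel_size = pixel_size), class = "kdna_region")

  with_seed(seed, {
    pos <- .sample_radial(region, n_emitters, law)
    qd0 <- matrix(0, ny, nx)
    if (n_emitters > 0) {
      for (k in seq_len(n_emitters)) {
        dx2 <- (xg - pos[k, 1])^2 + (yg - pos[k, 2])^2
        qd0 <- qd0 + qd_peak * exp(-dx2 / (2 * psf_sigma^2))
      }
    }
    dna_sm <- .from_eb(EBImage::gblur(.as_eb(dna0), sigma = psf_sigma))
    mk <- function(clean) {
      arr <- array(0, dim = c(ny, nx, n_frames))
      for (f in seq_len(n_frames))
        arr[, , f] <- if (noise)
          matrix(stats::rpois(ny * nx, as.vector(clean) + background), ny, nx)
        else clean
      arr
    }
    movie <- structure(list(dna = mk(dna_sm), qd = mk(qd0),
                            pixel_size = pixel_size,
                            frame_interval = frame_interval),
                       class = "labelled_movie")
    r_true <- if (n_emitters > 0)
      distance_to_boundary(pos, region) else numeric(0)
    truth <- structure(list(
      positions_px = pos,
      positions_um = pos * pixel_size,
      r_over_r0 = r_true / region$r0,
      radial_law = law, region = region, seed = seed),
      class = "ground_truth")
    list(movie = movie, truth = truth)
  })
}

## stratified pixel sampling by radial law + in-pixel jitter
.sample_radial <- function(region, n, law) {
  if (n == 0) return(matrix(numeric(0), 0, 2, dimnames = list(NULL, c("x", "y"))))
  idx <- which(region$mask, arr.ind = TRUE)
  px <- idx[, 2] - 1; py <- idx[, 1] - 1
  rr <- cpp_min_dist(px, py, as.numeric(region$boundary[, 1]),
                     as.numeric(region$boundary[, 2])) / region$r0
  pick <- switch(law$type,
    uniform = sample.int(length(px), n, replace = TRUE),
    peripheral = {
      outer_set <- which(rr <= law$shell_fraction)
      inner_set <- which(rr > law$shell_fraction)
      in_outer <- stats::runif(n) < law$p_outer
      k <- integer(n)
      if (any(in_outer))
        k[in_outer] <- outer_set[sample.int(length(outer_set),
                                            sum(in_outer), replace = TRUE)]
      if (any(!in_outer))
        k[!in_outer] <- inner_set[sample.int(length(inner_set),
                                             sum(!in_outer), replace = TRUE)]
      k
    },
    central = {
      set <- which(rr >= 0.5)
      set[sample.int(length(set), n, replace = TRUE)]
    })
  ## jitter inside the pixel but keep the point in the same (mask) pixel;
  ## re-draw jitter that would push a point out of its radial stratum so
  ## the placement law holds for the continuous positions, not just the
  ## pixel centres
  pos <- cbind(x = px[pick] + stats::runif(n, -0.499, 0.499),
               y = py[pick] + stats::runif(n, -0.499, 0.499))
  in_stratum <- function(rr_pt, k) {
    switch(law$type,
           uniform = rep(TRUE, length(rr_pt)),
           peripheral = ifelse(rr[pick[k]] <= law$shell_fraction,
                               rr_pt <= law$shell_fraction,
                               rr_pt > law$shell_fraction),
           central = rr_pt >= 0.5)
  }
  for (it in 1:20) {
    rr_pt <- cpp_min_dist(pos[, 1], pos[, 2],
                          as.numeric(region$boundary[, 1]),
                          as.numeric(region$boundary[, 2])) / region$r0
    bad <- which(!in_stratum(rr_pt, seq_len(n)))
    if (length(bad) == 0) break
    if (it < 20) {
      pos[bad, 1] <- px[pick[bad]] + stats::runif(length(bad), -0.499, 0.499)
      pos[bad, 2] <- py[pick[bad]] + stats::runif(length(bad), -0.499, 0.499)
    } else {
      pos[bad, 1] <- px[pick[bad]]
      pos[bad, 2] <- py[pick[bad]]
    }
  }
  pos
}
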