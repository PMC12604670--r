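## Radial enrichment profiles: observed vs random-deposition null.
##
## Distances r to the nearest boundary pixel are normalised by r0 (maximum
## boundary-to-centroid radius), so r/r0 = 0 at the rim and ~1 at the
## centre; the profile is the per-bin ratio of the observed and null
## probability density functions.

#' Relative-frequency enrichment profile
#'
#' Bins observed and null boundary distances on `r/r0` in `[0, 1]` and
#' forms the per-bin ratio of their normalised histograms. A ratio of 1
#' means the observed localisations are as frequent as expected under
#' uniform random deposition; > 1 means enrichment.
#'
#' Distances marginally above `r0` (possible for non-convex masks) are
#' clipped into the final bin with a warning. Bins where the null pdf is
#' zero get `NA` ("undefined"), never `Inf`.
#'
#' @param observed Numeric vector of observed spot distances (pixels).
#' @param null Numeric vector of null distances (pixels), e.g. from
#'   [sample_null()].
#' @param r0 Normalisation radius in pixels.
#' @param bins Number of equal-width bins on `[0, 1]` (default 10), or a
#'   vector of bin edges partitioning `[0, 1]`.
#' @return An `enrichment_profile`: data frame with `bin_lo`, `bin_hi`,
#'   `observed_pdf`, `null_pdf`, `relative_frequency`, with attributes
#'   `n_obs`, `n_null`, `r0`.
#' @export
enrichment <- function(observed, null, r0, bins = 10) {
  observed <- observed[!is.na(observed)]
  null <- null[!is.na(null)]
  stopifnot(r0 > 0, length(observed) > 0, length(null) > 0)
  edges <- if (length(bins) == 1) seq(0, 1, length.out = bins + 1) else sort(bins)
  stopifnot(abs(edges[1]) < 1e-12, abs(edges[length(edges)] - 1) < 1e-12)
  rr_obs <- observed / r0
  rr_null <- null / r0
  if (any(rr_obs > 1) || any(rr_null > 1)) {
    warning("distances exceeding r0 clipped into the final bin")
    rr_obs <- pmin(rr_obs, 1)
    rr_null <- pmin(rr_null, 1)
  }
  cut1 <- function(v) {
    i <- findInterval(v, edges, rightmost.closed = TRUE, left.open = FALSE)
    i[i > length(edges) - 1] <- length(edges) - 1
    tabulate(i, nbins = length(edges) - 1)
  }
  obs_pdf <- cut1(rr_obs) / length(rr_obs)
  null_pdf <- cut1(rr_null) / length(rr_null)
  ratio <- ifelse(null_pdf > 0, obs_pdf / null_pdf, NA_real_)
  out <- data.frame(bin_lo = edges[-length(edges)], bin_hi = edges[-1],
                    observed_pdf = obs_pdf, null_pdf = null_pdf,
                    relative_frequency = ratio)
  structure(out, n_obs = length(rr_obs), n_null = length(rr_null), r0 = r0,
            class = c("enrichment_profile", "data.frame"))
}

#' Aggregate enrichment profiles across structures
#'
#' Per-bin mean and standard deviation of the relative frequency across
#' several kDNA networks (each profile computed on identical bin edges).
#'
#' @param profiles List of [enrichment()] results with matching bins.
#' @return Data frame with `bin_lo`, `bin_hi`, `mean_rf`, `sd_rf`,
#'   `n_kdna` (profiles contributing a defined value per bin).
#' @export
aggregate_enrichment <- function(profiles) {
  stopifnot(length(profiles) >= 1,
            all(vapply(profiles, inherits, TRUE, "enrichment_profile")))
  edges0 <- profiles[[1]][, c("bin_lo", "bin_hi")]
  for (p in profiles)
    stopifnot(isTRUE(all.equal(p[, c("bin_lo", "bin_hi")], edges0,
                               check.attributes = FALSE)))
  rf <- sapply(profiles, function(p) p$relative_frequency)
  rf <- matrix(rf, nrow = nrow(edges0))
  data.frame(edges0,
             mean_rf = rowMeans(rf, na.rm = TRUE),
             sd_rf = apply(rf, 1, stats::sd, na.rm = TRUE),
             n_kdna = rowSums(!is.na(rf)))
}

#' Detect bright spots in a quantum-dot channel image
#'
#' Finds local intensity maxima above a threshold, enforces a minimum
#' separation (the brighter detection wins; closer emitters merge into one
#' detection), and refines each to a sub-pixel intensity-weighted centroid.
#'
#' @param qd_image Numeric matrix, the QD channel frame.
#' @param min_separation Minimum distance between detections in pixels.
#' @param threshold Absolute intensity threshold; default
#'   `mean + 4 * sd` of the smoothed image.
#' @param region Optional [segment_region()] result; detections outside its
#'   mask get `inside = FALSE`.
#' @param pixel_size Micrometres per pixel (for the `x_um`, `y_um` columns).
#' @param frame Frame index stored in the table.
#' @return A `spot_table` data frame: `x_px`, `y_px`, `x_um`, `y_um`,
#'   `frame`, `intensity`, `inside`. May have zero rows.
#' @export
detect_spots <- function(qd_image, min_separation = 3, threshold = NULL,
                         region = NULL, pixel_size = 1, frame = 0L) {
  stopifnot(is.matrix(qd_image))
  sm <- if (min_separation > 1)
    .from_eb(EBImage::gblur(.as_eb(qd_image), sigma = 1)) else qd_image
  thr <- threshold %||% (mean(sm) + 4 * stats::sd(sm))
  cand <- which(sm > thr, arr.ind = TRUE)
  empty <- data.frame(x_px = numeric(0), y_px = numeric(0), x_um = numeric(0),
                      y_um = numeric(0), frame = integer(0),
                      intensity = numeric(0), inside = logical(0))
  class(empty) <- c("spot_table", "data.frame")
  if (nrow(cand) == 0) return(empty)
  ord <- order(sm[cand], decreasing = TRUE)
  cand <- cand[ord, , drop = FALSE]
  acc <- matrix(numeric(0), 0, 2)  # (row, col) of accepted peaks
  for (k in seq_len(nrow(cand))) {
    p <- cand[k, ]
    if (nrow(acc) == 0 ||
        min((acc[, 1] - p[1])^2 + (acc[, 2] - p[2])^2) >= min_separation^2)
      acc <- rbind(acc, p)
  }
  w <- max(1L, floor(min_separation / 2))
  ny <- nrow(qd_image); nx <- ncol(qd_image)
  res <- t(apply(acc, 1, function(p) {
    ri <- max(1, p[1] - w):min(ny, p[1] + w)
    ci <- max(1, p[2] - w):min(nx, p[2] + w)
    win <- qd_image[ri, ci, drop = FALSE] - min(qd_image[ri, ci])
    s <- sum(win)
    if (s <= 0) return(c(p[2] - 1, p[1] - 1, qd_image[p[1], p[2]]))
    cx <- sum(t(win) * (ci - 1)) / s   # x = column - 1
    cy <- sum(win * (ri - 1)) / s      # y = row - 1
    c(cx, cy, sum(qd_image[ri, ci]))
  }))
  out <- data.frame(x_px = res[, 1], y_px = res[, 2],
                    x_um = res[, 1] * pixel_size, y_um = res[, 2] * pixel_size,
                    frame = as.integer(frame), intensity = res[, 3],
                    inside = TRUE)
  if (!is.null(region))
    out$inside <- .inside_mask(cbind(out$x_px, out$y_px), region$mask)
  class(out) <- c("spot_table", "data.frame")
  out
}
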