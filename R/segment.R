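## Segmentation of the DNA (kDNA) channel and boundary geometry.
##
## Image convention used throughout the package: a single frame is a base R
## matrix indexed [row, col] = [y + 1, x + 1]; coordinates (x, y) are 0-based
## with integer pixel centres, so pixel (0, 0) is the top-left matrix entry.
## Movies are arrays with dim c(ny, nx, n_frames).

## EBImage stores images [x, y]; these two helpers keep the conversion in one
## place.
.as_eb <- function(m) EBImage::Image(t(m))
.from_eb <- function(im) t(as.array(im))

#' Segment the kDNA region from a DNA-channel image
#'
#' Gaussian-smooths the image, thresholds it (Otsu by default), keeps the
#' largest connected foreground component, and extracts its boundary,
#' centroid and normalisation radius `r0` (the maximum distance of a
#' boundary pixel from the centroid).
#'
#' @param image Numeric matrix, a single DNA-channel frame (`[y, x]`).
#' @param blur_sigma Gaussian smoothing sigma in pixels.
#' @param threshold_method `"otsu"` (parameter-free) or a numeric threshold
#'   on the smoothed, `[0, 1]`-rescaled image.
#' @param pixel_size Physical pixel size in micrometres per pixel.
#' @return An object of class `kdna_region`: list with `mask` (logical
#'   matrix), `boundary` (n x 2 matrix of 0-based `(x, y)` pixel
#'   coordinates), `centroid` (`(x, y)` in pixels), `r0` (pixels) and
#'   `pixel_size`.
#' @export
segment_region <- function(image, blur_sigma = 2, threshold_method = "otsu",
                           pixel_size = 1) {
  stopifnot(is.matrix(image), all(is.finite(image)))
  rng <- range(image)
  if (rng[1] == rng[2])
    stop("no region found: image is constant")
  img01 <- (image - rng[1]) / (rng[2] - rng[1])
  sm <- if (blur_sigma > 0) .from_eb(EBImage::gblur(.as_eb(img01), sigma = blur_sigma))
        else img01
  sm <- pmin(pmax(sm, 0), 1)
  thr <- if (identical(threshold_method, "otsu")) {
    EBImage::otsu(.as_eb(sm))
  } else if (is.numeric(threshold_method)) {
    threshold_method
  } else stop("unknown threshold_method: ", threshold_method)
  mask <- sm > thr
  if (!any(mask)) stop("no region found: empty foreground after thresholding")
  lab <- .from_eb(EBImage::bwlabel(.as_eb(mask)))
  sizes <- tabulate(lab[lab > 0])
  mask <- lab == which.max(sizes)
  boundary <- extract_boundary(mask)
  ## binary centroid of the mask (robust to uneven staining)
  idx <- which(mask, arr.ind = TRUE)
  centroid <- c(x = mean(idx[, 2]) - 1, y = mean(idx[, 1]) - 1)
  r0 <- sqrt(max((boundary[, 1] - centroid[1])^2 + (boundary[, 2] - centroid[2])^2))
  structure(list(mask = mask, boundary = boundary, centroid = centroid,
                 r0 = r0, pixel_size = pixel_size),
            class = "kdna_region")
}

#' @export
print.kdna_region <- function(x, ...) {
  cat("kdna_region:", sum(x$mask), "mask px,", nrow(x$boundary), "boundary px,",
      sprintf("centroid (%.1f, %.1f) px, r0 = %.2f px (%.3f um)\n",
              x$centroid[1], x$centroid[2], x$r0, x$r0 * x$pixel_size))
  invisible(x)
}

#' Extract the boundary pixels of a binary mask
#'
#' A foreground pixel belongs to the boundary when at least one of its
#' 4-neighbours is background (or lies outside the image), giving the
#' 8-connected rim of the mask with no interior pixels.
#'
#' @param mask Logical matrix.
#' @return n x 2 integer matrix of 0-based `(x, y)` boundary coordinates.
#' @export
extract_boundary <- function(mask) {
  stopifnot(is.matrix(mask))
  mask <- mask > 0
  if (!any(mask)) stop("mask has no foreground pixel")
  ny <- nrow(mask); nx <- ncol(mask)
  pad <- matrix(FALSE, ny + 2, nx + 2)
  pad[2:(ny + 1), 2:(nx + 1)] <- mask
  core <- pad[2:(ny + 1), 2:(nx + 1)]
  interior <- core &
    pad[1:ny, 2:(nx + 1)] & pad[3:(ny + 2), 2:(nx + 1)] &
    pad[2:(ny + 1), 1:nx] & pad[2:(ny + 1), 3:(nx + 2)]
  idx <- which(core & !interior, arr.ind = TRUE)
  cbind(x = idx[, 2] - 1L, y = idx[, 1] - 1L)
}

#' Euclidean distance of spots to the nearest boundary pixel
#'
#' For each spot, the minimum Euclidean distance (in pixels) to any boundary
#' pixel of the region. Spots whose containing pixel lies outside the mask
#' are excluded from the analysis and get `NA`.
#'
#' @param spots Two-column matrix or data frame of `(x, y)` spot positions
#'   in 0-based pixel coordinates (sub-pixel allowed), or a `spot_table`.
#' @param region A [segment_region()] result.
#' @return Numeric vector of distances in pixels (`NA` for outside spots).
#' @export
distance_to_boundary <- function(spots, region) {
  stopifnot(inherits(region, "kdna_region"))
  xy <- .spot_xy(spots)
  if (nrow(xy) == 0) return(numeric(0))
  bx <- region$boundary[, 1]; by <- region$boundary[, 2]
  inside <- .inside_mask(xy, region$mask)
  d <- rep(NA_real_, nrow(xy))
  if (any(inside)) {
    d[inside] <- cpp_min_dist(xy[inside, 1], xy[inside, 2],
                              as.numeric(bx), as.numeric(by))
  }
  d
}

.spot_xy <- function(spots) {
  if (is.data.frame(spots)) {
    cols <- if (all(c("x_px", "y_px") %in% names(spots))) c("x_px", "y_px")
            else c("x", "y")
    as.matrix(spots[, cols, drop = FALSE])
  } else {
    m <- as.matrix(spots)
    stopifnot(ncol(m) >= 2)
    m[, 1:2, drop = FALSE]
  }
}

.inside_mask <- function(xy, mask) {
  i <- round(xy[, 2]) + 1; j <- round(xy[, 1]) + 1
  ok <- i >= 1 & i <= nrow(mask) & j >= 1 & j <= ncol(mask)
  ins <- ok
  ins[ok] <- mask[cbind(i[ok], j[ok])]
  ins
}

#' Sample the uniform random-deposition null inside a region
#'
#' Draws `multiplier * n_spots` points uniformly over the mask (uniform over
#' mask pixels with uniform jitter inside each pixel) and returns their
#' distances to the nearest boundary pixel, i.e. the null distance
#' distribution against which observed localisations are compared.
#'
#' @param region A [segment_region()] result.
#' @param n_spots Number of observed spots.
#' @param multiplier How many null points per observed spot (default 100).
#' @param seed Integer seed; fixed seed gives identical draws.
#' @return Numeric vector of `multiplier * n_spots` distances in pixels.
#' @export
sample_null <- function(region, n_spots, multiplier = 100, seed = NULL) {
  stopifnot(inherits(region, "kdna_region"), multiplier >= 1, n_spots >= 0)
  n <- as.integer(multiplier) * as.integer(n_spots)
  if (n == 0) return(numeric(0))
  idx <- which(region$mask, arr.ind = TRUE)
  with_seed(seed, {
    k <- sample.int(nrow(idx), n, replace = TRUE)
    x <- (idx[k, 2] - 1) + runif(n, -0.5, 0.5)
    y <- (idx[k, 1] - 1) + runif(n, -0.5, 0.5)
    distance_to_boundary(cbind(x, y), region)
  })
}
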