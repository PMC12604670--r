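## File interfaces: TIFF movies, CSV spot/track tables, LAMMPS data files.

#' Write a two-channel labelled movie as multi-page TIFF + JSON sidecar
#'
#' Pages are ordered frame-major, channel-minor (TCYX: frame 1 channel 1,
#' frame 1 channel 2, frame 2 channel 1, ...), ImageJ-compatible.
#' Calibration (pixel size, frame interval, channel names) goes to
#' `<path>.json`.
#'
#' @param movie A `labelled_movie` (from [make_kdna_image()]).
#' @param path Output TIFF path.
#' @return `path`, invisibly.
#' @export
write_labelled_movie <- function(movie, path) {
  if (!requireNamespace("tiff", quietly = TRUE))
    stop("the 'tiff' package is required to write TIFF files")
  stopifnot(inherits(movie, "labelled_movie"))
  nf <- dim(movie$dna)[3]
  scale <- max(movie$dna, movie$qd, 1)
  pages <- vector("list", 2 * nf)
  for (f in seq_len(nf)) {
    pages[[2 * f - 1]] <- movie$dna[, , f] / scale
    pages[[2 * f]] <- movie$qd[, , f] / scale
  }
  tiff::writeTIFF(pages, path, bits.per.sample = 16)
  if (requireNamespace("jsonlite", quietly = TRUE)) {
    jsonlite::write_json(
      list(pixel_size_um = movie$pixel_size,
           frame_interval_s = movie$frame_interval,
           n_frames = nf, channels = c("dna", "qd"),
           intensity_scale = scale, axis_order = "TCYX"),
      paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' Read a two-channel labelled movie written by [write_labelled_movie()]
#' @param path TIFF path (the `<path>.json` sidecar is read when present).
#' @return A `labelled_movie`.
#' @export
read_labelled_movie <- function(path) {
  if (!requireNamespace("tiff", quietly = TRUE))
    stop("the 'tiff' package is required to read TIFF files")
  pages <- tiff::readTIFF(path, all = TRUE)
  meta <- if (file.exists(paste0(path, ".json")) &&
              requireNamespace("jsonlite", quietly = TRUE))
    jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  else list(pixel_size_um = 1, frame_interval_s = 1, intensity_scale = 1)
  nf <- length(pages) / 2
  dna <- array(0, c(dim(pages[[1]]), nf))
  qd <- array(0, c(dim(pages[[1]]), nf))
  for (f in seq_len(nf)) {
    dna[, , f] <- pages[[2 * f - 1]] * meta$intensity_scale
    qd[, , f] <- pages[[2 * f]] * meta$intensity_scale
  }
  structure(list(dna = dna, qd = qd, pixel_size = meta$pixel_size_um,
                 frame_interval = meta$frame_interval_s),
            class = "labelled_movie")
}

#' Write / read spot tables and track sets as CSV
#'
#' Columns `frame, x_um, y_um, id` (plus any extra columns present);
#' the frame interval is stored in a header comment line.
#'
#' @param x A `spot_table` or [track_set()].
#' @param path CSV path.
#' @return `path` invisibly (writer); a [track_set()] or data frame
#'   (reader).
#' @export
write_track_csv <- function(x, path) {
  con <- file(path, "w")
  on.exit(close(con))
  fi <- attr(x, "frame_interval")
  if (!is.null(fi)) writeLines(sprintf("# frame_interval_s=%.10g", fi), con)
  utils::write.csv(as.data.frame(x), con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_track_csv
#' @export
read_track_csv <- function(path) {
  first <- readLines(path, n = 1)
  fi <- NULL
  skip <- 0
  if (startsWith(first, "#")) {
    skip <- 1
    m <- regmatches(first, regexec("frame_interval_s=([0-9.eE+-]+)", first))[[1]]
    if (length(m) == 2) fi <- as.numeric(m[2])
  }
  df <- utils::read.csv(path, skip = skip)
  if (all(c("id", "frame", "x_um", "y_um") %in% names(df)))
    track_set(df, frame_interval = fi %||% (1 / 8))
  else df
}

#' Write a network as a LAMMPS data file (atom style angle)
#'
#' Atoms carry the ring id as molecule id; FENE bonds close each ring and
#' one angle per bead supports the bending potential. A JSON topology
#' sidecar (`<path>.json`) records ring classes, link edges with chirality
#' and the network mode.
#'
#' @param net An `olympic_network`.
#' @param path Output path.
#' @param box_pad Padding of the simulation box around the beads (sigma).
#' @return `path`, invisibly.
#' @export
write_lammps_data <- function(net, path, box_pad = 10) {
  stopifnot(inherits(net, "olympic_network"))
  pos <- net_positions(net)
  len <- ring_lengths(net)
  off <- c(0L, cumsum(len))
  n <- nrow(pos)
  types <- unlist(lapply(seq_along(net$rings), function(r)
    rep(if (net$rings[[r]]$class == "mini") 1L else 2L, len[r])))
  mol <- rep(seq_along(len), len)
  bonds <- do.call(rbind, lapply(seq_along(len), function(r) {
    i <- (off[r] + 1):off[r + 1]
    cbind(i, c(i[-1], i[1]))
  }))
  angles <- do.call(rbind, lapply(seq_along(len), function(r) {
    i <- (off[r] + 1):off[r + 1]
    cbind(i, c(i[-1], i[1]), c(i[-(1:2)], i[1:2]))
  }))
  lo <- apply(pos, 2, min) - box_pad
  hi <- apply(pos, 2, max) + box_pad
  con <- file(path, "w")
  on.exit(close(con))
  w <- function(...) writeLines(sprintf(...), con)
  w("LAMMPS data file: catenated ring network (%s), %d rings", net$mode,
    length(len))
  w("")
  w("%d atoms", n); w("%d bonds", nrow(bonds)); w("%d angles", nrow(angles))
  w("2 atom types"); w("1 bond types"); w("1 angle types")
  w("")
  w("%.6f %.6f xlo xhi", lo[1], hi[1])
  w("%.6f %.6f ylo yhi", lo[2], hi[2])
  w("%.6f %.6f zlo zhi", lo[3], hi[3])
  w(""); w("Masses"); w(""); w("1 1.0"); w("2 1.0")
  w(""); w("Atoms # angle"); w("")
  for (i in seq_len(n))
    w("%d %d %d %.8f %.8f %.8f", i, mol[i], types[i],
      pos[i, 1], pos[i, 2], pos[i, 3])
  w(""); w("Bonds"); w("")
  for (i in seq_len(nrow(bonds)))
    w("%d 1 %d %d", i, bonds[i, 1], bonds[i, 2])
  w(""); w("Angles"); w("")
  for (i in seq_len(nrow(angles)))
    w("%d 1 %d %d %d", i, angles[i, 1], angles[i, 2], angles[i, 3])
  if (requireNamespace("jsonlite", quietly = TRUE)) {
    jsonlite::write_json(
      list(mode = net$mode,
           ring_class = vapply(net$rings, `[[`, "", "class"),
           ring_len = len,
           link_edges = net$link_edges,
           seed = net$seed),
      paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' Write a trajectory as an XYZ file
#' @param trajectory List of n x 3 frames.
#' @param path Output path.
#' @param types Optional per-bead element labels.
#' @return `path`, invisibly.
#' @export
write_xyz <- function(trajectory, path, types = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  for (f in seq_along(trajectory)) {
    fr <- trajectory[[f]]
    ty <- types %||% rep("C", nrow(fr))
    writeLines(c(sprintf("%d", nrow(fr)), sprintf("frame %d", f)), con)
    writeLines(sprintf("%s %.6f %.6f %.6f", ty, fr[, 1], fr[, 2], fr[, 3]),
               con)
  }
  invisible(path)
}

#' Write a triangle mesh in OFF format
#' @param mesh A [disk_mesh()] or [triangulate_points()] result.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_off <- function(mesh, path) {
  stopifnot(inherits(mesh, "disk_mesh"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("OFF", con)
  writeLines(sprintf("%d %d 0", nrow(mesh$vertices), nrow(mesh$triangles)),
             con)
  writeLines(sprintf("%.8f %.8f %.8f", mesh$vertices[, 1],
                     mesh$vertices[, 2], mesh$vertices[, 3]), con)
  writeLines(sprintf("3 %d %d %d", mesh$triangles[, 1] - 1L,
                     mesh$triangles[, 2] - 1L, mesh$triangles[, 3] - 1L), con)
  invisible(path)
}
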