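# Polar <-> Cartesian geometry, color mapping and raster I/O.
#
# Coordinate conventions: a polar frame is a depth_samples x n_alines matrix
# (rows = depth along the A-line starting at the catheter, columns = A-line
# angle). Angle 0 maps to the Cartesian +x axis and angles increase
# counter-clockwise. Public depth / A-line coordinates are 0-based.

#' Resample a polar OCT frame onto a Cartesian grid
#'
#' Maps a depth x angle raster to a square image centered on the catheter
#' axis. A Cartesian pixel at radius `r` and angle `theta` samples the polar
#' raster at depth `r * depth_samples / (out_size/2)` and A-line
#' `theta / (2*pi) * n_alines`, with bilinear interpolation and angular
#' wrap-around. Pixels beyond the maximum imaging depth are 0.
#'
#' @param frame Numeric matrix, depth x A-lines, finite and non-negative.
#' @param out_size Side length in pixels of the square output (default 1024).
#' @return `out_size` x `out_size` numeric matrix with attribute `center`
#'   (the catheter axis, in pixel units).
#' @export
polar_to_cartesian <- function(frame, out_size = 1024L) {
  stopifnot(is.matrix(frame))
  if (out_size < 2L) stop("out_size must be at least 2")
  if (any(!is.finite(frame)) || any(frame < 0))
    stop("frame intensities must be finite and non-negative")
  H <- nrow(frame); W <- ncol(frame)
  ctr <- (out_size + 1) / 2
  xs <- seq_len(out_size) - ctr
  x <- matrix(xs, out_size, out_size, byrow = TRUE)
  y <- matrix(-xs, out_size, out_size)           # row 1 is the top
  r <- sqrt(x^2 + y^2)
  theta <- atan2(y, x) %% (2 * pi)

  depth <- r * H / (out_size / 2)                # 0-based, continuous
  aline <- theta / (2 * pi) * W
  inside <- depth <= (H - 1)

  d0 <- pmin(floor(depth), H - 1)
  fd <- depth - d0
  a0 <- floor(aline)
  fa <- aline - a0

  i0 <- pmin(d0 + 1, H); i1 <- pmin(d0 + 2, H)
  j0 <- wrap_index(a0 + 1, W); j1 <- wrap_index(a0 + 2, W)
  v <- (1 - fd) * ((1 - fa) * frame[cbind(c(i0), c(j0))] +
                   fa * frame[cbind(c(i0), c(j1))]) +
       fd * ((1 - fa) * frame[cbind(c(i1), c(j0))] +
             fa * frame[cbind(c(i1), c(j1))])
  out <- matrix(v, out_size, out_size)
  out[!inside] <- 0
  attr(out, "center") <- c(x = ctr, y = ctr)
  out
}

oct_colormaps <- function() {
  list(
    sepia = list(pos = c(0, 0.35, 0.7, 1),
                 r = c(0, 0.36, 0.80, 1.00),
                 g = c(0, 0.24, 0.60, 0.95),
                 b = c(0, 0.12, 0.32, 0.80)),
    gray = list(pos = c(0, 1), r = c(0, 1), g = c(0, 1), b = c(0, 1))
  )
}

#' Map a normalized grayscale raster to RGB
#'
#' Applies a fixed monotone colormap (luminance increases with intensity)
#' so that phantom and clinical rasters share one consistent RGB rendering,
#' the space in which the network operates.
#'
#' @param gray Numeric matrix with values in `[0, 1]`.
#' @param map_name One of `"sepia"` (default) or `"gray"`. `"gray"`
#'   replicates the input on all three channels.
#' @return H x W x 3 numeric array.
#' @export
apply_colormap <- function(gray, map_name = "sepia") {
  maps <- oct_colormaps()
  if (!map_name %in% names(maps))
    stop(sprintf("unknown colormap '%s'; available: %s", map_name,
                 paste(names(maps), collapse = ", ")))
  if (any(gray < -1e-9) || any(gray > 1 + 1e-9))
    stop("gray values must be normalized to [0, 1]")
  g <- pmin(pmax(gray, 0), 1)
  m <- maps[[map_name]]
  out <- array(0, c(dim(g), 3L))
  out[, , 1] <- approx(m$pos, m$r, xout = g)$y
  out[, , 2] <- approx(m$pos, m$g, xout = g)$y
  out[, , 3] <- approx(m$pos, m$b, xout = g)$y
  out
}

#' Read / write per-pixel tissue label maps
#'
#' Label maps hold one class per pixel (0 background, 1 fibrous,
#' 2 calcified, 3 lipid) and are stored as 8-bit grayscale PNG with the raw
#' class index as the pixel value. Reading validates the range and names any
#' offending value.
#'
#' @param lm Integer matrix with values in `{0, 1, 2, 3}`.
#' @param path File path.
#' @return `read_label_map` returns an integer matrix.
#' @export
write_label_map <- function(lm, path) {
  lm <- as.matrix(lm)
  bad <- setdiff(unique(as.integer(lm)), 0:3)
  if (length(bad))
    stop(sprintf("label map contains invalid class index %d", bad[1]))
  png::writePNG(lm / 255, path)
  invisible(path)
}

#' @rdname write_label_map
#' @export
read_label_map <- function(path) {
  x <- png::readPNG(path)
  if (length(dim(x)) == 3L) x <- x[, , 1]
  v <- matrix(as.integer(round(x * 255)), nrow(x), ncol(x))
  bad <- setdiff(unique(as.integer(v)), 0:3)
  if (length(bad))
    stop(sprintf("label file contains invalid class index %d", bad[1]))
  v
}

#' Read / write polar frames as 16-bit TIFF
#'
#' Intensities are stored as `value / max_value` at 16-bit depth; arbitrary
#' units, `max_value` defaults to 255.
#' @param frame Numeric matrix.
#' @param path File path.
#' @param max_value Intensity mapped to the top of the 16-bit range.
#' @export
write_polar_frame <- function(frame, path, max_value = 255) {
  tiff::writeTIFF(pmin(pmax(frame / max_value, 0), 1), path,
                  bits.per.sample = 16L)
  invisible(path)
}

#' @rdname write_polar_frame
#' @export
read_polar_frame <- function(path, max_value = 255) {
  x <- tiff::readTIFF(path)
  if (length(dim(x)) == 3L) x <- x[, , 1]
  x * max_value
}

#' Export contours as CSV
#'
#' One row per (frame, A-line) with the 0-based lumen depth.
#' @param contours Matrix n_frames x n_alines of 0-based depths.
#' @param path File path.
#' @export
write_contour_csv <- function(contours, path) {
  contours <- rbind(contours)
  df <- data.frame(
    frame = rep(seq_len(nrow(contours)) - 1L, each = ncol(contours)),
    a_line = rep(seq_len(ncol(contours)) - 1L, times = nrow(contours)),
    depth = as.vector(t(contours))
  )
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Overlay predicted tissue classes on an RGB raster
#'
#' Blends the standard display colors for plaque components (red fibrous,
#' green calcified, blue lipid) over the image; background is untouched.
#'
#' @param rgb H x W x 3 array in `[0, 1]`.
#' @param labels Integer label matrix of the same spatial size.
#' @param path Optional PNG output path.
#' @param alpha Blend weight of the class color.
#' @return The blended H x W x 3 array, invisibly if written to file.
#' @export
export_overlay <- function(rgb, labels, path = NULL, alpha = 0.45) {
  stopifnot(all(dim(rgb)[1:2] == dim(labels)))
  cols <- rbind(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))
  out <- rgb
  for (k in 1:3) {
    m <- labels == k
    if (!any(m)) next
    for (ch in 1:3)
      out[, , ch][m] <- (1 - alpha) * out[, , ch][m] + alpha * cols[k, ch]
  }
  if (!is.null(path)) {
    png::writePNG(out, path)
    return(invisible(out))
  }
  out
}
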