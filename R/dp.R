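# Lumen-boundary and guidewire-band detection by dynamic programming, and
# ROI-band construction. All public depth / A-line coordinates are 0-based.

#' Axial gradient cost for lumen detection
#'
#' The lumen border is the strongest dark-to-bright step along each A-line,
#' so the cost at depth d is the negative axial intensity difference
#' `-(I(d) - I(d-1))`; minimizing total cost maximizes the step. The first
#' row has no predecessor and gets cost 0.
#'
#' @param frame Numeric depth x A-line matrix.
#' @return Cost matrix of the same size, finite everywhere.
#' @export
gradient_cost <- function(frame) {
  stopifnot(is.matrix(frame))
  if (any(!is.finite(frame))) stop("frame must be finite")
  H <- nrow(frame)
  cost <- matrix(0, H, ncol(frame))
  if (H > 1) cost[2:H, ] <- -(frame[2:H, , drop = FALSE] -
                              frame[1:(H - 1), , drop = FALSE])
  cost
}

#' Minimum-cost smooth path across the columns of a cost raster
#'
#' Selects one row per column minimizing the total cost subject to a
#' smoothness constraint: adjacent columns may differ by at most `max_step`
#' rows. With `periodic = TRUE` the first and last columns must also satisfy
#' the constraint (a closed contour); this is solved exactly by restarting
#' the recursion from every possible first-column row, or by the cheaper
#' column-tripling heuristic for large rasters. Cost ties are broken toward
#' the smaller row index.
#'
#' @param cost Numeric rows x cols matrix, finite.
#' @param max_step Maximum row change between adjacent columns (>= 0).
#' @param periodic Require the wrap pair of columns to obey the constraint.
#' @param wrap_rows Treat the row axis as circular (used for the angular
#'   axis in guidewire tracing).
#' @param method `"exact"`, `"tripled"`, or `"auto"` (exact below a size
#'   threshold, tripling above).
#' @return List with `path` (1-based row per column) and `total` cost.
#' @export
dp_min_path <- function(cost, max_step, periodic = FALSE, wrap_rows = FALSE,
                        method = c("auto", "exact", "tripled")) {
  method <- match.arg(method)
  stopifnot(is.matrix(cost))
  if (any(!is.finite(cost))) stop("cost must be finite")
  if (max_step < 0) stop("max_step must be non-negative")
  R <- nrow(cost); C <- ncol(cost)
  if (method == "auto")
    method <- if (!periodic || as.double(R)^2 * C * (2 * max_step + 1) <= 5e8)
      "exact" else "tripled"
  if (!periodic || method == "exact" || C == 1L) {
    res <- cpp_dp_min_path(cost, as.integer(max_step), periodic, wrap_rows)
  } else {
    wide <- cpp_dp_min_path(cbind(cost, cost, cost), as.integer(max_step),
                            FALSE, wrap_rows)
    path0 <- wide$path[C + seq_len(C)]
    res <- list(path = path0, total = sum(cost[cbind(path0 + 1L, seq_len(C))]))
  }
  list(path = res$path + 1L, total = res$total)
}

#' Detect the lumen contour of one polar frame
#'
#' Runs the smooth minimum-cost path on the axial-gradient cost of the
#' frame, producing one lumen depth per A-line (a closed contour when
#' `periodic = TRUE`). If guidewire columns are supplied, their depths are
#' replaced by linear interpolation between the flanking non-guidewire
#' columns, since tissue signal is shadowed there.
#'
#' @param frame Numeric depth x A-line matrix.
#' @param max_step Smoothness bound, pixels per A-line (default 2).
#' @param periodic Closed-contour constraint (default TRUE).
#' @param guidewire_cols Optional integer vector of 0-based A-line indices
#'   shadowed by the guidewire.
#' @return Integer vector of 0-based lumen depths, one per A-line.
#' @export
detect_lumen <- function(frame, max_step = 2L, periodic = TRUE,
                         guidewire_cols = NULL) {
  path <- dp_min_path(gradient_cost(frame), max_step, periodic)$path
  contour <- path - 1L
  if (length(guidewire_cols)) {
    W <- ncol(frame)
    gw <- sort(unique(wrap_index(as.integer(guidewire_cols) + 1L, W)))
    contour <- interpolate_over(contour, gw)
  }
  as.integer(contour)
}

# Replace values at 1-based positions `gw` of a circular sequence by linear
# interpolation between the nearest non-gw flanks.
interpolate_over <- function(x, gw) {
  n <- length(x)
  keep <- setdiff(seq_len(n), gw)
  if (!length(keep)) return(x)
  for (i in gw) {
    dl <- (i - keep) %% n
    dr <- (keep - i) %% n
    l <- keep[which.min(dl)]; r <- keep[which.min(dr)]
    wl <- min(dl); wr <- min(dr)
    x[i] <- round((wr * x[l] + wl * x[r]) / (wl + wr))
  }
  x
}

#' Detect the guidewire shadow band across a pullback
#'
#' Builds the (A-lines x frames) map of per-A-line mean intensity — over a
#' pullback the shadow forms a continuous dark band across frames — and
#' traces it with the smooth minimum-cost path (angular axis circular,
#' intensity itself as cost). Around the traced A-line of each frame the
#' band is grown outward until the column mean recovers above
#' `recovery_fraction` of the global median; the band center is the midpoint
#' of that interval. If the scan is inconclusive the half-width falls back
#' to 5% of the A-line count.
#'
#' @param frames List of polar frames (one pullback).
#' @param max_step Angular smoothness of the band across frames.
#' @param recovery_fraction Intensity fraction of the global median at which
#'   the band is considered ended.
#' @return List with `center` (0-based A-line per frame), `half_width`
#'   (A-lines, scalar), and `detectability` (median-to-band intensity
#'   ratio; near 1 means no dark band exists).
#' @export
detect_guidewire <- function(frames, max_step = 2L, recovery_fraction = 0.6) {
  stopifnot(length(frames) >= 1)
  M <- vapply(frames, colMeans, numeric(ncol(frames[[1]])))
  M <- matrix(M, ncol = length(frames))         # A-lines x frames
  W <- nrow(M)
  path <- dp_min_path(M, max_step, periodic = FALSE, wrap_rows = TRUE)$path
  thr <- recovery_fraction * median(M)
  centers <- integer(length(frames))
  hws <- integer(length(frames))
  for (f in seq_along(frames)) {
    a0 <- path[f]
    lo <- 0L
    while (lo < W - 1L && M[wrap_index(a0 - lo - 1L, W), f] < thr) lo <- lo + 1L
    hi <- 0L
    while (hi < W - 1L && M[wrap_index(a0 + hi + 1L, W), f] < thr) hi <- hi + 1L
    if (lo + hi >= W - 1L || M[a0, f] >= thr) {     # inconclusive scan
      centers[f] <- a0 - 1L
      hws[f] <- max(1L, round(0.05 * W))
    } else {
      centers[f] <- wrap_index(a0 + round((hi - lo) / 2), W) - 1L
      hws[f] <- max(1L, ceiling((lo + hi) / 2))
    }
  }
  band_mean <- mean(M[cbind(path, seq_along(frames))])
  list(center = centers, half_width = as.integer(round(median(hws))),
       detectability = band_mean / median(M))
}

#' A-line columns covered by a guidewire band in one frame
#'
#' @param band Result of [detect_guidewire()] (or a compatible list).
#' @param frame_idx Frame number, 1-based.
#' @param n_alines Number of A-lines.
#' @return Integer vector of 0-based column indices.
#' @export
guidewire_columns <- function(band, frame_idx, n_alines) {
  ctr <- band$center[frame_idx]
  sort(unique(wrap_index(ctr + seq(-band$half_width, band$half_width) + 1L,
                         n_alines))) - 1L
}

#' Build the region-of-interest band beyond the lumen
#'
#' Marks, for every non-guidewire A-line, the depths from the lumen contour
#' down to `roi_depth` pixels beyond it (clipped at the bottom of the
#' raster) — the band in which OCT penetration makes tissue classification
#' meaningful. The default depth is 100 pixels.
#'
#' @param contour Integer vector of 0-based lumen depths per A-line.
#' @param depth_samples Number of depth samples of the raster.
#' @param guidewire_cols Optional 0-based A-line indices to exclude.
#' @param roi_depth Band depth in pixels (> 0), default 100.
#' @return Logical depth x A-line matrix.
#' @export
build_roi <- function(contour, depth_samples, guidewire_cols = NULL,
                      roi_depth = 100L) {
  if (roi_depth <= 0) stop("roi_depth must be positive")
  W <- length(contour)
  mask <- matrix(FALSE, depth_samples, W)
  for (a in seq_len(W)) {
    lo <- contour[a] + 1L
    hi <- min(depth_samples, contour[a] + roi_depth)
    if (lo <= hi) mask[lo:hi, a] <- TRUE
  }
  if (length(guidewire_cols))
    mask[, wrap_index(as.integer(guidewire_cols) + 1L, W)] <- FALSE
  mask
}
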