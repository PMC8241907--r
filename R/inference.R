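# Convolutionalized whole-image prediction, cascade inference, ROI masking
# and small-region post-processing.
#
# Because every layer is a valid convolution or a stride-1 max pool and the
# normalization statistics are frozen at inference, feeding a full image
# produces, at every pixel, exactly the distribution the patch classifier
# would produce on the receptive-field patch centered there. That
# equivalence is this module's defining contract.

#' Dense whole-image prediction
#'
#' Runs the network convolutionally over a full polar RGB raster. With
#' `pad = TRUE` (default) the raster is padded by half the receptive field
#' (depth axis reflected, angular axis wrapped, matching patch extraction)
#' so the output probability map is pixel-aligned with the input; with
#' `pad = FALSE` the map covers only the valid interior (a 65x65 input
#' yields a 33x33 map).
#'
#' @param net A `twopath_net`.
#' @param image H x W x C numeric array; C must match the network.
#' @param pad Reflect/wrap-pad the borders (default TRUE).
#' @return A `class_prob_map`: list with `probs` (H' x W' x n_classes, each
#'   pixel summing to 1) and `offset` (margin of the valid region relative
#'   to the input; 0 when padded).
#' @export
predict_dense <- function(net, image, pad = TRUE) {
  d <- dim(image)
  if (length(d) != 3L) stop("image must be an H x W x C array")
  rf <- receptive_field(net$spec)
  p <- (rf - 1L) %/% 2L
  if (pad) {
    image <- pad_polar(image, p)
    offset <- 0L
  } else {
    if (d[1] < rf || d[2] < rf)
      stop(sprintf("image (%dx%d) smaller than the receptive field (%d); enable padding",
                   d[1], d[2], rf))
    offset <- p
  }
  probs <- net_forward(net, image, mode = "eval")$probs
  dim(probs) <- dim(probs)[1:3]
  structure(list(probs = probs, offset = offset), class = "class_prob_map")
}

#' Cascade inference over a full image
#'
#' Two dense passes: the stage-1 probability map is computed once for the
#' whole image, concatenated channel-wise with the RGB raster (aligned to
#' pixel centers), and passed through stage 2. Pixels are labeled by the
#' maximum-probability class (ties toward the higher class index in the
#' order background < fibrous < calcified < lipid); every pixel outside the
#' ROI is set to background regardless of the network output.
#'
#' @param pair A `cascade_pair`.
#' @param image H x W x 3 polar RGB raster.
#' @param roi Optional logical H x W ROI mask.
#' @return List with `labels` (integer H x W map) and `probs`
#'   (H x W x n_classes array).
#' @export
predict_cascade <- function(pair, image, roi = NULL) {
  stopifnot(inherits(pair, "cascade_pair"))
  d <- dim(image)
  if (!is.null(roi) && !all(d[1:2] == dim(roi)))
    stop("roi shape does not match the image")
  m1 <- predict_dense(pair$stage1, image, pad = TRUE)
  img7 <- array(0, c(d[1], d[2], 3L + dim(m1$probs)[3]))
  img7[, , 1:3] <- image
  img7[, , 3L + seq_len(dim(m1$probs)[3])] <- m1$probs
  m2 <- predict_dense(pair$stage2, img7, pad = TRUE)
  labels <- channel_argmax(m2$probs)
  if (!is.null(roi)) labels[!roi] <- 0L
  list(labels = labels, probs = m2$probs)
}

#' Remove small isolated regions from a label map
#'
#' Each 4-connected component (with angular wrap-around across the polar
#' seam) of a non-background class with area below `min_area` is reassigned
#' to the majority class among its surrounding pixels (background on a
#' tie); larger components are untouched. `min_area = 0` is the identity.
#' The operation is idempotent at fixed `min_area`.
#'
#' @param lm Integer label map.
#' @param min_area Minimum component area in pixels (>= 0).
#' @param wrap_cols Connect components across the angular seam.
#' @return Integer label map.
#' @export
remove_small_regions <- function(lm, min_area = 64L, wrap_cols = TRUE) {
  if (min_area < 0) stop("min_area must be non-negative")
  if (min_area == 0) return(lm)
  lm <- matrix(as.integer(lm), nrow(lm), ncol(lm))
  comp <- cpp_label_components(lm, wrap_cols)
  sizes <- tabulate(comp)
  out <- lm
  H <- nrow(lm); W <- ncol(lm)
  for (id in which(sizes < min_area)) {
    cells <- which(comp == id)
    cls <- lm[cells[1]]
    if (cls == 0L) next
    rows <- (cells - 1L) %% H + 1L
    cols <- (cells - 1L) %/% H + 1L
    nb_r <- c(rows - 1L, rows + 1L, rows, rows)
    nb_c <- c(cols, cols, cols - 1L, cols + 1L)
    keep <- nb_r >= 1L & nb_r <= H
    nb_r <- nb_r[keep]
    nb_c <- wrap_index(nb_c[keep], W)
    if (!wrap_cols) {
      k2 <- c(cols, cols, cols - 1L, cols + 1L)[keep] >= 1L &
            c(cols, cols, cols - 1L, cols + 1L)[keep] <= W
      nb_r <- nb_r[k2]; nb_c <- nb_c[k2]
    }
    nb <- cbind(nb_r, nb_c)
    outside <- comp[nb] != id
    if (!any(outside)) next
    nb_classes <- lm[nb[outside, , drop = FALSE]]
    tab <- table(nb_classes)
    top <- as.integer(names(tab)[tab == max(tab)])
    out[cells] <- if (length(top) > 1L) 0L else top
  }
  out
}
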