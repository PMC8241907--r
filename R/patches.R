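# Labeled patch extraction, flip augmentation, exact class balancing and
# train/validation splitting.
#
# A patch set holds N patches of size M x M x C (M odd so the center pixel
# is well defined), the class of each patch's center pixel, and provenance
# (source frame, 0-based center row/col, flip code, source index).

new_patch_set <- function(patches, labels, provenance, size, channels) {
  structure(list(patches = patches, labels = as.integer(labels),
                 provenance = provenance, size = as.integer(size),
                 channels = as.integer(channels)),
            class = "patch_set")
}

#' @export
print.patch_set <- function(x, ...) {
  cat(sprintf("patch_set: %d patches of %dx%dx%d\n", n_patches(x),
              x$size, x$size, x$channels))
  print(class_counts(x))
  invisible(x)
}

#' Number of patches / per-class counts of a patch set
#' @param ps A `patch_set`.
#' @return `n_patches`: integer. `class_counts`: named integer vector over
#'   classes 0-3.
#' @export
n_patches <- function(ps) length(ps$labels)

#' @rdname n_patches
#' @export
class_counts <- function(ps) {
  out <- integer(4)
  names(out) <- names(OCT_CLASSES)
  t <- table(factor(ps$labels, levels = 0:3))
  out[] <- as.integer(t)
  out
}

empty_patch_set <- function(size, channels) {
  new_patch_set(array(0, c(size, size, channels, 0L)), integer(0),
                data.frame(frame = integer(0), row = integer(0),
                           col = integer(0), flip = character(0),
                           source = integer(0)),
                size, channels)
}

#' Extract labeled patches from a polar raster
#'
#' Emits one patch for every ROI pixel on the stride grid; the patch label
#' is the label-map class at its center pixel. Patches are taken from the
#' padded raster (depth axis reflected, angular axis wrapped across the
#' seam) so every ROI pixel is eligible, including those near borders. An
#' empty ROI yields an empty set.
#'
#' @param image H x W x C numeric array (RGB polar raster).
#' @param labels Integer H x W label map.
#' @param roi Logical H x W mask of eligible center pixels.
#' @param size Odd patch side length (33 or 65 by default usage).
#' @param stride Grid stride in pixels (default 2).
#' @param frame_id Identifier recorded in provenance.
#' @param max_per_class Optional cap per class; a random subsample is kept.
#' @param seed Seed for the subsampling draw.
#' @return A `patch_set`.
#' @export
extract_patches <- function(image, labels, roi, size = 33L, stride = 2L,
                            frame_id = 1L, max_per_class = Inf, seed = NULL) {
  d <- dim(image)
  if (length(d) != 3L) stop("image must be an H x W x C array")
  if (!all(d[1:2] == dim(labels)) || !all(d[1:2] == dim(roi)))
    stop("image, labels and roi must have congruent shapes")
  if (size %% 2L == 0L) stop("patch size must be odd")
  grid <- which(roi &
                ((row(roi) - 1L) %% stride == 0L) &
                ((col(roi) - 1L) %% stride == 0L), arr.ind = TRUE)
  if (nrow(grid) == 0L) return(empty_patch_set(size, d[3]))
  lab <- labels[grid]
  if (is.finite(max_per_class)) {
    keep <- with_seed(seed, unlist(lapply(split(seq_along(lab), lab),
      function(ix) if (length(ix) > max_per_class)
        sample(ix, max_per_class) else ix)))
    keep <- sort(keep)
    grid <- grid[keep, , drop = FALSE]
    lab <- lab[keep]
  }
  p <- (size - 1L) %/% 2L
  padded <- pad_polar(image, p)
  n <- nrow(grid)
  patches <- array(0, c(size, size, d[3], n))
  for (i in seq_len(n)) {
    r <- grid[i, 1]; c <- grid[i, 2]
    patches[, , , i] <- padded[r:(r + 2L * p), c:(c + 2L * p), , drop = FALSE]
  }
  prov <- data.frame(frame = frame_id, row = grid[, 1] - 1L,
                     col = grid[, 2] - 1L, flip = "none",
                     source = seq_len(n))
  new_patch_set(patches, lab, prov, size, d[3])
}

#' Extract patches of one frame at given centers
#'
#' Rebuilds a patch set co-centered with an existing one (e.g. the 65-pixel
#' companions of a balanced 33-pixel set): slices the padded raster at the
#' provided 0-based centers and applies the recorded flip codes.
#'
#' @param image H x W x C array.
#' @param size Odd patch side length.
#' @param centers Data frame with columns `row`, `col`, `flip`, `source`
#'   (and optionally `frame`), as in patch-set provenance.
#' @param labels Integer labels to carry over, one per center.
#' @param frame_id Identifier recorded in provenance.
#' @return A `patch_set` in the order of `centers`.
#' @export
extract_patches_at <- function(image, size, centers, labels, frame_id = 1L) {
  d <- dim(image)
  p <- (size - 1L) %/% 2L
  padded <- pad_polar(image, p)
  n <- nrow(centers)
  patches <- array(0, c(size, size, d[3], n))
  for (i in seq_len(n)) {
    r <- centers$row[i] + 1L; c <- centers$col[i] + 1L
    pt <- padded[r:(r + 2L * p), c:(c + 2L * p), , drop = FALSE]
    dim(pt) <- c(size, size, d[3])
    patches[, , , i] <- flip_patch(pt, centers$flip[i])
  }
  prov <- data.frame(frame = frame_id, row = centers$row, col = centers$col,
                     flip = centers$flip, source = centers$source)
  new_patch_set(patches, labels, prov, size, d[3])
}

flip_patch <- function(patch, code) {
  switch(code,
         none = patch,
         h = patch[, rev(seq_len(dim(patch)[2])), , drop = FALSE],
         v = patch[rev(seq_len(dim(patch)[1])), , , drop = FALSE],
         stop(sprintf("unknown flip code '%s'", code)))
}

#' Flip a patch along the x and y directions
#'
#' Returns the two flip augmentations (horizontal, i.e. along x, and
#' vertical, along y) of a patch; the center pixel — and hence the label —
#' is unchanged because the side length is odd.
#'
#' @param patch M x M x C numeric array.
#' @return List with elements `h` and `v`.
#' @export
flip_augment <- function(patch) {
  stopifnot(length(dim(patch)) == 3L)
  list(h = flip_patch(patch, "h"), v = flip_patch(patch, "v"))
}

#' Balance class counts exactly by flip augmentation
#'
#' Raises every class present to the maximum original class count: deficits
#' are filled first with horizontal/vertical flips of randomly chosen
#' originals of that class (each original contributes at most its two
#' distinct flips), then — if still short — by resampling with replacement.
#' No majority patch is removed; an already balanced set is returned
#' unchanged.
#'
#' @param ps A `patch_set`.
#' @param classes Classes to balance; defaults to those present. Requesting
#'   a class with no patches is an error naming the class.
#' @param seed Seed for the augmentation draws.
#' @return A `patch_set` with exactly equal per-class counts.
#' @export
balance_by_augmentation <- function(ps, classes = NULL, seed = NULL) {
  counts <- table(factor(ps$labels, levels = 0:3))
  if (is.null(classes)) classes <- as.integer(names(counts))[counts > 0]
  for (k in classes) if (counts[[as.character(k)]] == 0L)
    stop(sprintf("cannot balance: class %d (%s) has no patches", k,
                 names(OCT_CLASSES)[k + 1]))
  target <- max(counts[as.character(classes)])
  if (all(counts[as.character(classes)] == target)) return(ps)

  with_seed(seed, {
    add_patches <- list(); add_labels <- integer(0); add_prov <- list()
    for (k in classes) {
      deficit <- target - counts[[as.character(k)]]
      if (deficit == 0L) next
      orig <- which(ps$labels == k & ps$provenance$flip == "none")
      if (!length(orig)) orig <- which(ps$labels == k)
      pairs <- expand.grid(src = orig, flip = c("h", "v"),
                           stringsAsFactors = FALSE)
      take <- min(deficit, nrow(pairs))
      sel <- pairs[sample.int(nrow(pairs), take), , drop = FALSE]
      for (i in seq_len(nrow(sel))) {
        s <- sel$src[i]
        pt <- ps$patches[, , , s, drop = FALSE]
        dim(pt) <- dim(pt)[1:3]
        add_patches[[length(add_patches) + 1L]] <- flip_patch(pt, sel$flip[i])
        add_labels <- c(add_labels, k)
        pr <- ps$provenance[s, ]
        pr$flip <- sel$flip[i]; pr$source <- s
        add_prov[[length(add_prov) + 1L]] <- pr
      }
      extra <- deficit - take
      if (extra > 0L) {  # resample with replacement
        pool <- which(ps$labels == k)
        rs <- sample(pool, extra, replace = TRUE)
        for (s in rs) {
          pt <- ps$patches[, , , s, drop = FALSE]
          dim(pt) <- dim(pt)[1:3]
          add_patches[[length(add_patches) + 1L]] <- pt
          add_labels <- c(add_labels, k)
          pr <- ps$provenance[s, ]
          pr$source <- s
          add_prov[[length(add_prov) + 1L]] <- pr
        }
      }
    }
    n_new <- length(add_patches)
    out <- array(0, c(ps$size, ps$size, ps$channels, n_patches(ps) + n_new))
    if (n_patches(ps)) out[, , , seq_len(n_patches(ps))] <- ps$patches
    for (i in seq_len(n_new)) out[, , , n_patches(ps) + i] <- add_patches[[i]]
    new_patch_set(out, c(ps$labels, add_labels),
                  rbind(ps$provenance, do.call(rbind, add_prov)),
                  ps$size, ps$channels)
  })
}

#' Split a patch set into training and validation parts
#'
#' The split is made at the level of source frames — no frame contributes
#' patches to both sides — and aims at `fraction` of the patches in the
#' validation part, stratified by class as far as whole frames allow.
#'
#' @param ps A `patch_set`.
#' @param fraction Validation fraction in (0, 1).
#' @param seed Seed for the frame shuffle.
#' @return List with `train` and `val` patch sets and `val_frames`.
#' @export
split_validation <- function(ps, fraction, seed = NULL) {
  if (fraction <= 0 || fraction >= 1) stop("fraction must be in (0, 1)")
  frames <- unique(ps$provenance$frame)
  if (length(frames) < 2L)
    stop("cannot split: all patches come from a single source image")
  with_seed(seed, {
    ord <- sample(frames)
    target <- fraction * n_patches(ps)
    val_frames <- c()
    tot <- 0
    for (f in ord) {
      if (tot >= target) break
      if (length(val_frames) == length(frames) - 1L) break  # keep train side
      val_frames <- c(val_frames, f)
      tot <- tot + sum(ps$provenance$frame == f)
    }
    in_val <- ps$provenance$frame %in% val_frames
    list(train = subset_patch_set(ps, which(!in_val)),
         val = subset_patch_set(ps, which(in_val)),
         val_frames = val_frames)
  })
}

#' Subset / combine patch sets
#' @param ps A `patch_set`.
#' @param idx Integer indices of patches to keep.
#' @return A `patch_set`.
#' @export
subset_patch_set <- function(ps, idx) {
  new_patch_set(ps$patches[, , , idx, drop = FALSE], ps$labels[idx],
                ps$provenance[idx, , drop = FALSE], ps$size, ps$channels)
}

#' @rdname subset_patch_set
#' @param ... `patch_set` objects with identical size and channels.
#' @export
bind_patch_sets <- function(...) {
  sets <- list(...)
  sets <- sets[vapply(sets, n_patches, 1L) > 0]
  if (!length(sets)) stop("no non-empty patch sets to bind")
  size <- sets[[1]]$size; ch <- sets[[1]]$channels
  for (s in sets) stopifnot(s$size == size, s$channels == ch)
  n <- sum(vapply(sets, n_patches, 1L))
  out <- array(0, c(size, size, ch, n))
  at <- 0L
  for (s in sets) {
    k <- n_patches(s)
    out[, , , at + seq_len(k)] <- s$patches
    at <- at + k
  }
  new_patch_set(out, unlist(lapply(sets, `[[`, "labels")),
                do.call(rbind, lapply(sets, `[[`, "provenance")), size, ch)
}

#' Serialize a patch set
#'
#' R-native serialization; the write/read round trip is bit-exact.
#' @param ps A `patch_set`.
#' @param path File path.
#' @export
write_patch_set <- function(ps, path) {
  saveRDS(ps, path)
  invisible(path)
}

#' @rdname write_patch_set
#' @export
read_patch_set <- function(path) readRDS(path)
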