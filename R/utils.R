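# Internal helpers shared across modules.

# Evaluate `expr` under a fixed RNG seed without disturbing the caller's
# RNG stream. `seed = NULL` leaves the stream alone.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  expr
}

# Padded row/column lookup tables for polar rasters: rows (depth) reflect
# without repeating the edge sample, columns (angle) wrap.
reflect_index <- function(i, n) {
  # i may run from 1-p .. n+p; requires p <= n-1
  i <- ifelse(i < 1L, 2L - i, i)
  i <- ifelse(i > n, 2L * n - i, i)
  i
}

wrap_index <- function(i, n) ((i - 1L) %% n) + 1L

# Pad an (H, W) matrix or (H, W, C) array by `p` pixels: depth axis
# reflected, angular axis wrapped across the 0/n_alines seam.
pad_polar <- function(x, p) {
  d <- dim(x)
  H <- d[1]; W <- d[2]
  if (p > H - 1L) stop("padding exceeds raster depth")
  ri <- reflect_index(seq.int(1L - p, H + p), H)
  ci <- wrap_index(seq.int(1L - p, W + p), W)
  if (length(d) == 2L) x[ri, ci, drop = FALSE] else x[ri, ci, , drop = FALSE]
}

# argmax over the channel axis of an (H, W, K) probability array, ties
# resolved toward the larger class index.
channel_argmax <- function(probs) {
  d <- dim(probs)
  m <- matrix(probs, nrow = d[1] * d[2], ncol = d[3])
  matrix(max.col(m, ties.method = "last") - 1L, d[1], d[2])
}

stopifnot_scalar <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop(sprintf("'%s' must be a finite scalar", name))
}
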