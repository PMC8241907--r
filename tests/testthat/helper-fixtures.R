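# Shared fixtures and independent oracles. Oracles here are deliberately
# naive (enumeration, per-pixel loops) and independent of the package's
# implementation paths.

# slim architecture for fast tests; geometry identical to the default
tiny_spec <- function(input_channels = 3L, dropout_rate = 0.2) {
  twopath_spec(input_channels = input_channels,
               maps_local = c(3L, 3L, 3L), maps_global = 6L,
               dropout_rate = dropout_rate)
}

# exhaustive minimum-cost feasible path by enumeration of all row choices
brute_force_dp <- function(cost, max_step, periodic = FALSE,
                           wrap_rows = FALSE) {
  R <- nrow(cost); C <- ncol(cost)
  combos <- as.matrix(expand.grid(rep(list(seq_len(R)), C)))
  stepok <- function(a, b) {
    d <- abs(a - b)
    if (wrap_rows) d <- pmin(d, R - d)
    d <= max_step
  }
  ok <- rep(TRUE, nrow(combos))
  for (cc in 2:C) ok <- ok & stepok(combos[, cc], combos[, cc - 1])
  if (periodic) ok <- ok & stepok(combos[, 1], combos[, C])
  combos <- combos[ok, , drop = FALSE]
  tot <- rowSums(matrix(cost[cbind(as.vector(combos),
                                   rep(seq_len(C), each = nrow(combos)))],
                        nrow(combos)))
  min(tot)
}

# reduced noise-free phantom, cached per test run
noise_free_phantom <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- generate_pullback(phantom_spec(n_frames = 3L, noise_sd = 0,
                                               seed = 11L))
    cache
  }
})

# synthetic patch set with per-class counts (classes 0, 1, ... in order);
# class signal is mean intensity so sets are usable for toy training
make_patch_set <- function(counts, size = 33L, channels = 3L,
                           n_frames = 4L, seed = 1L,
                           means = c(0.2, 0.8, 0.45, 0.6)) {
  withr_seed <- function(expr) { set.seed(seed); expr }
  withr_seed({
    labels <- rep(seq_along(counts) - 1L, counts)
    n <- length(labels)
    patches <- array(0, c(size, size, channels, n))
    for (i in seq_len(n))
      patches[, , , i] <- means[labels[i] + 1L] +
        array(rnorm(size * size * channels, 0, 0.05),
              c(size, size, channels))
    prov <- data.frame(frame = rep_len(seq_len(n_frames), n),
                       row = sample(200L, n, replace = TRUE),
                       col = sample(100L, n, replace = TRUE),
                       flip = "none", source = seq_len(n))
    octplaque:::new_patch_set(patches, labels, prov, size, channels)
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a
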