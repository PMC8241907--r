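# The two-pathway patch network.
#
# Local pathway: conv 7x7 -> max pool (stride 1) -> conv 3x3 -> max pool
# (stride 1) -> conv 3x3. Global pathway: one conv 15x15. Both pathways use
# ReLU followed by feature-map normalization; their spatial outputs are
# equal by construction (each shrinks a 33x33 patch by 14 pixels), are
# concatenated, pass through dropout and a convolutional output layer with
# one kernel per class, and end in a channel-wise softmax. All convolutions
# are valid (no padding), all pooling is max with stride 1, so the network
# applied to a whole image is exactly the patch classifier slid over every
# pixel.

#' Architecture description of the two-pathway network
#'
#' Declarative spec from which networks are built and receptive fields
#' computed. The local pathway has three convolutions (7x7 then two 3x3)
#' interleaved with two stride-1 max-pool layers; the global pathway is a
#' single 15x15 convolution with more feature maps than the last local
#' layer. The output layer kernel is sized so that a `patch_size` input
#' collapses to a single class distribution; the composed receptive field
#' equals `patch_size` (33 by default).
#'
#' @param input_channels 3 for RGB patches, 7 for the cascade second stage.
#' @param n_classes Number of output kernels; 4 (three tissue classes plus
#'   background).
#' @param maps_local Feature maps of the three local convolutions.
#' @param maps_global Feature maps of the global convolution; must exceed
#'   the last local count.
#' @param kernels_local,pool_sizes,kernel_global Layer geometry.
#' @param patch_size Training patch side; also the receptive field.
#' @param norm_epsilon Variance floor `t` of the normalization step.
#' @param dropout_rate Dropout probability on the concatenated maps.
#' @return A `twopath_spec`.
#' @export
twopath_spec <- function(input_channels = 3L, n_classes = 4L,
                         maps_local = c(64L, 64L, 64L), maps_global = 160L,
                         kernels_local = c(7L, 3L, 3L),
                         pool_sizes = c(4L, 2L), kernel_global = 15L,
                         patch_size = 33L, norm_epsilon = 1e-5,
                         dropout_rate = 0.3) {
  local_shrink <- sum(kernels_local - 1L) + sum(pool_sizes - 1L)
  global_shrink <- kernel_global - 1L
  if (local_shrink != global_shrink)
    stop(sprintf(paste0("pathway outputs are spatially incompatible: for a ",
                        "%dx%d input the local path gives %dx%d but the ",
                        "global path gives %dx%d"),
                 patch_size, patch_size,
                 patch_size - local_shrink, patch_size - local_shrink,
                 patch_size - global_shrink, patch_size - global_shrink))
  if (maps_global <= maps_local[length(maps_local)])
    stop("the global pathway must carry more feature maps than the last local layer")
  kernel_out <- patch_size - local_shrink
  if (kernel_out < 1) stop("patch_size too small for the pathway geometry")
  if (norm_epsilon <= 0) stop("norm_epsilon must be positive")
  structure(list(input_channels = as.integer(input_channels),
                 n_classes = as.integer(n_classes),
                 maps_local = as.integer(maps_local),
                 maps_global = as.integer(maps_global),
                 kernels_local = as.integer(kernels_local),
                 pool_sizes = as.integer(pool_sizes),
                 kernel_global = as.integer(kernel_global),
                 kernel_out = as.integer(kernel_out),
                 patch_size = as.integer(patch_size),
                 norm_epsilon = norm_epsilon,
                 dropout_rate = dropout_rate),
            class = "twopath_spec")
}

#' Receptive field of a stack of valid convolutions and stride-1 pools
#'
#' Each k x k convolution adds k-1 pixels and each stride-1 pool of size p
#' adds p-1 pixels to the receptive field.
#'
#' @param kernels Convolution kernel sizes, in order.
#' @param pools Pooling sizes, in order.
#' @return Receptive field side length in pixels.
#' @export
rf_from_layers <- function(kernels, pools = integer(0)) {
  1L + sum(kernels - 1L) + sum(pools - 1L)
}

#' Receptive field of a two-pathway spec
#'
#' @param spec A `twopath_spec`.
#' @return Pixels; 33 for the default spec.
#' @export
receptive_field <- function(spec) {
  rf_from_layers(c(spec$kernels_local, spec$kernel_out), spec$pool_sizes)
}

#' Feature-map normalization
#'
#' Standardizes a feature map to mean near 0 and variance near 1:
#' `(x - mu) / sqrt(sigma^2 + t)` with `mu`, `sigma^2` the map's own mean
#' and (population) variance and `t` a small constant preventing division
#' by zero. A constant map maps to all zeros.
#'
#' @param x Numeric array.
#' @param t Positive variance floor.
#' @return Array of the same shape.
#' @export
feature_normalize <- function(x, t = 1e-5) {
  if (t <= 0) stop("t must be positive")
  mu <- mean(x)
  v <- mean((x - mu)^2)
  (x - mu) / sqrt(v + t)
}

#' Numerically stable softmax
#'
#' `softmax(a)_i = exp(a_i) / sum_j exp(a_j)`, computed with
#' max-subtraction so large scores cannot overflow. The result is a
#' probability distribution: every element in (0, 1), summing to 1; adding
#' a constant to all scores leaves it unchanged.
#'
#' @param a Numeric vector of finite scores.
#' @return Numeric vector of the same length.
#' @export
softmax <- function(a) {
  if (any(!is.finite(a))) stop("scores must be finite")
  e <- exp(a - max(a))
  e / sum(e)
}

# softmax over the 3rd (channel) axis of an (H, W, K, N) array
softmax_channels <- function(x) {
  d <- dim(x)
  m <- matrix(aperm(x, c(3, 1, 2, 4)), nrow = d[3])
  m <- exp(sweep(m, 2, apply(m, 2, max)))
  m <- sweep(m, 2, colSums(m), "/")
  aperm(array(m, c(d[3], d[1], d[2], d[4])), c(2, 3, 1, 4))
}

he_init <- function(k, cin, cout) {
  array(rnorm(k * k * cin * cout, 0, sqrt(2 / (k * k * cin))),
        c(k, k, cin, cout))
}

#' Build a two-pathway network with random weights
#'
#' Weights are He-initialized from the current RNG stream (or `seed`);
#' biases start at zero. Normalization layers keep running mean/variance
#' statistics per feature map, initialized to 0/1, updated from batch
#' statistics during training and frozen at inference so the network is
#' exactly convolutional.
#'
#' @param spec A [twopath_spec()].
#' @param seed Optional seed for the weight draw.
#' @return A `twopath_net`.
#' @export
build_network <- function(spec, seed = NULL) {
  stopifnot(inherits(spec, "twopath_spec"))
  with_seed(seed, {
    m <- spec$maps_local
    params <- list(
      conv_l1 = list(W = he_init(spec$kernels_local[1], spec$input_channels, m[1]),
                     b = numeric(m[1])),
      conv_l2 = list(W = he_init(spec$kernels_local[2], m[1], m[2]),
                     b = numeric(m[2])),
      conv_l3 = list(W = he_init(spec$kernels_local[3], m[2], m[3]),
                     b = numeric(m[3])),
      conv_g = list(W = he_init(spec$kernel_global, spec$input_channels,
                                spec$maps_global),
                    b = numeric(spec$maps_global)),
      conv_out = list(W = he_init(spec$kernel_out, m[3] + spec$maps_global,
                                  spec$n_classes),
                      b = numeric(spec$n_classes)))
    norm <- list(l1 = new_norm_state(m[1]), l2 = new_norm_state(m[2]),
                 l3 = new_norm_state(m[3]), g = new_norm_state(spec$maps_global))
    structure(list(spec = spec, params = params, norm = norm),
              class = "twopath_net")
  })
}

new_norm_state <- function(ch) list(mean = numeric(ch), var = rep(1, ch))

#' @export
print.twopath_net <- function(x, ...) {
  s <- x$spec
  cat(sprintf(paste0("twopath_net: input %dch, local %s (k=%s, pools %s), ",
                     "global %d (k=%d), output %d kernels (k=%d), RF %d\n"),
              s$input_channels, paste(s$maps_local, collapse = "/"),
              paste(s$kernels_local, collapse = "/"),
              paste(s$pool_sizes, collapse = "/"),
              s$maps_global, s$kernel_global, s$n_classes, s$kernel_out,
              receptive_field(s)))
  invisible(x)
}

# ---- forward / backward -------------------------------------------------

as_batch <- function(x) {
  d <- dim(x)
  if (length(d) == 3L) dim(x) <- c(d, 1L)
  x
}

relu <- function(x) {
  x[x < 0] <- 0
  x
}

# Normalization layer. Training mode standardizes each feature map with the
# batch statistics over (H, W, N) and updates the running statistics;
# inference uses the frozen running statistics so the operation is
# position-independent (a pure per-channel affine map), which keeps dense
# whole-image inference exactly equal to patchwise classification.
norm_forward <- function(x, state, t, mode, momentum = 0.1) {
  d <- dim(x)
  m <- matrix(aperm(x, c(1, 2, 4, 3)), ncol = d[3])  # (H*W*N) x C
  if (mode == "train") {
    mu <- colMeans(m)
    xc <- sweep(m, 2, mu)
    v <- colMeans(xc^2)
    state$mean <- (1 - momentum) * state$mean + momentum * mu
    state$var <- (1 - momentum) * state$var + momentum * v
  } else {
    mu <- state$mean
    v <- state$var
    xc <- sweep(m, 2, mu)
  }
  xhat <- sweep(xc, 2, sqrt(v + t), "/")
  out <- aperm(array(xhat, c(d[1], d[2], d[4], d[3])), c(1, 2, 4, 3))
  list(out = out, state = state, xhat = xhat, var = v, mode = mode)
}

norm_backward <- function(dout, cache, t) {
  d <- dim(dout)
  dm <- matrix(aperm(dout, c(1, 2, 4, 3)), ncol = d[3])
  inv <- 1 / sqrt(cache$var + t)
  if (cache$mode == "train") {
    xhat <- cache$xhat
    dx <- sweep(dm, 2, colMeans(dm)) -
      sweep(xhat, 2, colMeans(dm * xhat), "*")
    dx <- sweep(dx, 2, inv, "*")
  } else {
    dx <- sweep(dm, 2, inv, "*")
  }
  aperm(array(dx, c(d[1], d[2], d[4], d[3])), c(1, 2, 4, 3))
}

concat_channels <- function(a, b) {
  da <- dim(a); db <- dim(b)
  out <- array(0, c(da[1], da[2], da[3] + db[3], da[4]))
  out[, , seq_len(da[3]), ] <- a
  out[, , da[3] + seq_len(db[3]), ] <- b
  out
}

# Full forward pass. mode "train" uses batch normalization statistics and
# dropout (mask drawn from the current RNG stream); mode "eval" uses frozen
# statistics and no dropout. Returns probabilities, logits and (optionally)
# the caches needed for the backward pass.
net_forward <- function(net, x, mode = c("eval", "train"), keep_cache = FALSE) {
  mode <- match.arg(mode)
  x <- as_batch(x)
  if (dim(x)[3] != net$spec$input_channels)
    stop(sprintf("input has %d channels but the network expects %d",
                 dim(x)[3], net$spec$input_channels))
  s <- net$spec; p <- net$params; t <- s$norm_epsilon
  cache <- list()

  a1 <- cpp_conv_forward(x, p$conv_l1$W, p$conv_l1$b)
  r1 <- relu(a1)
  n1 <- norm_forward(r1, net$norm$l1, t, mode)
  pl1 <- cpp_maxpool_forward(n1$out, s$pool_sizes[1])
  a2 <- cpp_conv_forward(pl1$out, p$conv_l2$W, p$conv_l2$b)
  r2 <- relu(a2)
  n2 <- norm_forward(r2, net$norm$l2, t, mode)
  pl2 <- cpp_maxpool_forward(n2$out, s$pool_sizes[2])
  a3 <- cpp_conv_forward(pl2$out, p$conv_l3$W, p$conv_l3$b)
  r3 <- relu(a3)
  n3 <- norm_forward(r3, net$norm$l3, t, mode)

  ag <- cpp_conv_forward(x, p$conv_g$W, p$conv_g$b)
  rg <- relu(ag)
  ng <- norm_forward(rg, net$norm$g, t, mode)

  cat <- concat_channels(n3$out, ng$out)
  if (mode == "train" && s$dropout_rate > 0) {
    mask <- array((runif(length(cat)) >= s$dropout_rate) /
                    (1 - s$dropout_rate), dim(cat))
    catd <- cat * mask
  } else {
    mask <- NULL
    catd <- cat
  }
  logits <- cpp_conv_forward(catd, p$conv_out$W, p$conv_out$b)
  probs <- softmax_channels(logits)

  norm_states <- list(l1 = n1$state, l2 = n2$state, l3 = n3$state,
                      g = ng$state)
  if (keep_cache)
    cache <- list(x = x, a1 = a1, n1 = n1, pl1 = pl1, a2 = a2, n2 = n2,
                  pl2 = pl2, a3 = a3, n3 = n3, ag = ag, ng = ng,
                  catd = catd, mask = mask, n_local = dim(n3$out)[3])
  list(probs = probs, logits = logits, cache = cache,
       norm_states = norm_states)
}

# Backward pass from d(loss)/d(logits). Returns gradients for every weight
# tensor.
net_backward <- function(net, cache, dlogits) {
  s <- net$spec; p <- net$params; t <- s$norm_epsilon
  g_out <- cpp_conv_backward(cache$catd, p$conv_out$W, dlogits)
  dcat <- g_out$dinput
  if (!is.null(cache$mask)) dcat <- dcat * cache$mask
  nl <- cache$n_local
  dn3 <- dcat[, , seq_len(nl), , drop = FALSE]
  dng <- dcat[, , nl + seq_len(dim(dcat)[3] - nl), , drop = FALSE]

  dr3 <- norm_backward(dn3, cache$n3, t)
  dr3[cache$a3 <= 0] <- 0
  g3 <- cpp_conv_backward(cache$pl2$out, p$conv_l3$W, dr3)
  dp2 <- cpp_maxpool_backward(g3$dinput, cache$pl2$idx,
                              dim(cache$n2$out)[1], dim(cache$n2$out)[2])
  dr2 <- norm_backward(dp2, cache$n2, t)
  dr2[cache$a2 <= 0] <- 0
  g2 <- cpp_conv_backward(cache$pl1$out, p$conv_l2$W, dr2)
  dp1 <- cpp_maxpool_backward(g2$dinput, cache$pl1$idx,
                              dim(cache$n1$out)[1], dim(cache$n1$out)[2])
  dr1 <- norm_backward(dp1, cache$n1, t)
  dr1[cache$a1 <= 0] <- 0
  g1 <- cpp_conv_backward(cache$x, p$conv_l1$W, dr1)

  drg <- norm_backward(dng, cache$ng, t)
  drg[cache$ag <= 0] <- 0
  gg <- cpp_conv_backward(cache$x, p$conv_g$W, drg)

  list(conv_l1 = list(W = g1$dW, b = g1$db),
       conv_l2 = list(W = g2$dW, b = g2$db),
       conv_l3 = list(W = g3$dW, b = g3$db),
       conv_g = list(W = gg$dW, b = gg$db),
       conv_out = list(W = g_out$dW, b = g_out$db))
}

#' Classify a batch of patches
#'
#' Evaluation-mode forward pass; each `patch_size` input yields one class
#' distribution (positive probabilities summing to 1).
#'
#' @param net A `twopath_net`.
#' @param x Array (M, M, C) or (M, M, C, N).
#' @return N x n_classes matrix of probabilities.
#' @export
predict_patches <- function(net, x) {
  x <- as_batch(x)
  out <- net_forward(net, x, mode = "eval")$probs
  d <- dim(out)
  if (d[1] != 1L || d[2] != 1L)
    stop("input patches larger than the receptive field; use predict_dense")
  t(matrix(out, d[3], d[4]))
}

#' Serialize a network's architecture and weights
#'
#' Architecture to YAML, weights to R-native serialization.
#' @param net A `twopath_net`.
#' @param dir Output directory.
#' @export
write_network <- function(net, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  yaml::write_yaml(unclass(net$spec), file.path(dir, "spec.yaml"))
  saveRDS(net[c("params", "norm")], file.path(dir, "weights.rds"))
  invisible(dir)
}

#' @rdname write_network
#' @export
read_network <- function(dir) {
  sp <- yaml::read_yaml(file.path(dir, "spec.yaml"))
  spec <- do.call(twopath_spec, sp[setdiff(names(sp),
                                           c("kernel_out"))])
  w <- readRDS(file.path(dir, "weights.rds"))
  structure(list(spec = spec, params = w$params, norm = w$norm),
            class = "twopath_net")
}
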