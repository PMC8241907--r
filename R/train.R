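# Training: RMSprop on softmax cross-entropy, two-phase training (full fit
# on balanced patches, then output-layer-only refit on the natural class
# distribution), and cascade construction (stage-1 probability maps
# concatenated onto second-stage patches).

#' Training configuration
#'
#' RMSprop with squared-gradient decay 0.9 and categorical cross-entropy on
#' the softmax outputs.
#'
#' @param learning_rate Step size (> 0 allowed; 0 performs no update).
#' @param batch_size Patches per update.
#' @param epochs Passes over the training set.
#' @param squared_gradient_decay RMSprop decay of the squared-gradient
#'   accumulator, in (0, 1); default 0.9.
#' @param rmsprop_epsilon Denominator floor.
#' @param norm_momentum Update rate of the running normalization statistics.
#' @param seed Seed controlling shuffling, dropout and any weight draws.
#' @return A `train_config`.
#' @export
train_config <- function(learning_rate = 1e-4, batch_size = 128L,
                         epochs = 20L, squared_gradient_decay = 0.9,
                         rmsprop_epsilon = 1e-8, norm_momentum = 0.1,
                         seed = 1L) {
  if (learning_rate < 0) stop("learning_rate must be non-negative")
  if (squared_gradient_decay <= 0 || squared_gradient_decay >= 1)
    stop("squared_gradient_decay must be in (0, 1)")
  structure(list(learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs),
                 squared_gradient_decay = squared_gradient_decay,
                 rmsprop_epsilon = rmsprop_epsilon,
                 norm_momentum = norm_momentum,
                 seed = as.integer(seed)),
            class = "train_config")
}

labels_to_onehot <- function(labels, n_classes) {
  y <- matrix(0, n_classes, length(labels))
  y[cbind(labels + 1L, seq_along(labels))] <- 1
  y
}

new_rms_state <- function(params)
  lapply(params, function(p) lapply(p, function(w)
    if (is.null(dim(w))) numeric(length(w)) else array(0, dim(w))))

`%||%` <- function(a, b) if (is.null(a)) b else a

rmsprop_update <- function(params, grads, state, cfg, only = NULL) {
  for (nm in names(params)) {
    if (!is.null(only) && !nm %in% only) next
    for (fld in names(params[[nm]])) {
      g <- grads[[nm]][[fld]]
      v <- cfg$squared_gradient_decay * state[[nm]][[fld]] +
        (1 - cfg$squared_gradient_decay) * g^2
      state[[nm]][[fld]] <- v
      params[[nm]][[fld]] <- params[[nm]][[fld]] -
        cfg$learning_rate * g / (sqrt(v) + cfg$rmsprop_epsilon)
    }
  }
  list(params = params, state = state)
}

# cross-entropy loss and accuracy of eval-mode predictions on a patch set,
# computed in chunks to bound memory
eval_on_set <- function(net, ps, chunk = 256L) {
  n <- n_patches(ps)
  if (n == 0L) return(c(loss = NA_real_, acc = NA_real_))
  loss <- 0; correct <- 0
  for (at in seq(1L, n, by = chunk)) {
    idx <- at:min(n, at + chunk - 1L)
    pr <- predict_patches(net, ps$patches[, , , idx, drop = FALSE])
    py <- pr[cbind(seq_along(idx), ps$labels[idx] + 1L)]
    loss <- loss + sum(-log(pmax(py, 1e-12)))
    correct <- correct + sum(max.col(pr, ties.method = "last") - 1L ==
                               ps$labels[idx])
  }
  c(loss = loss / n, acc = correct / n)
}

#' Train a network on labeled patches
#'
#' Mini-batch RMSprop on categorical cross-entropy. Per-epoch training and
#' validation loss/accuracy are recorded; the weights with the best
#' validation accuracy (earliest epoch on ties) are returned. With a fixed
#' seed the run is reproducible.
#'
#' @param net A `twopath_net` whose input channels match the patches.
#' @param train_ps Training `patch_set`.
#' @param val_ps Optional validation `patch_set`.
#' @param cfg A [train_config()].
#' @param only Restrict updates to the named parameter tensors (used by
#'   phase-2 training); `NULL` trains everything.
#' @param verbose Print per-epoch metrics.
#' @return List with `net` (trained) and `history` (data frame).
#' @export
train_network <- function(net, train_ps, val_ps = NULL, cfg = train_config(),
                          only = NULL, verbose = FALSE) {
  if (train_ps$channels != net$spec$input_channels)
    stop(sprintf("patch channels (%d) do not match network input channels (%d)",
                 train_ps$channels, net$spec$input_channels))
  n <- n_patches(train_ps)
  if (n == 0L) stop("empty training set")
  state <- new_rms_state(net$params)
  hist <- list()
  best <- list(acc = -Inf, net = net)
  with_seed(cfg$seed, {
    for (epoch in seq_len(cfg$epochs)) {
      ord <- sample.int(n)
      ep_loss <- 0; ep_correct <- 0
      for (at in seq(1L, n, by = cfg$batch_size)) {
        idx <- ord[at:min(n, at + cfg$batch_size - 1L)]
        xb <- train_ps$patches[, , , idx, drop = FALSE]
        yb <- train_ps$labels[idx]
        fw <- net_forward(net, xb, mode = "train", keep_cache = TRUE)
        net$norm <- fw$norm_states
        pm <- matrix(fw$probs, net$spec$n_classes, length(idx))
        y <- labels_to_onehot(yb, net$spec$n_classes)
        py <- pm[cbind(yb + 1L, seq_along(idx))]
        ep_loss <- ep_loss + sum(-log(pmax(py, 1e-12)))
        ep_correct <- ep_correct +
          sum(max.col(t(pm), ties.method = "last") - 1L == yb)
        dlogits <- array((pm - y) / length(idx),
                         c(1L, 1L, net$spec$n_classes, length(idx)))
        grads <- net_backward(net, fw$cache, dlogits)
        up <- rmsprop_update(net$params, grads, state, cfg, only)
        net$params <- up$params
        state <- up$state
      }
      vm <- if (!is.null(val_ps)) eval_on_set(net, val_ps)
            else c(loss = NA_real_, acc = NA_real_)
      hist[[epoch]] <- data.frame(epoch = epoch, train_loss = ep_loss / n,
                                  train_acc = ep_correct / n,
                                  val_loss = vm[["loss"]],
                                  val_acc = vm[["acc"]])
      if (verbose)
        message(sprintf("epoch %d: train loss %.4f acc %.3f | val loss %s acc %s",
                        epoch, ep_loss / n, ep_correct / n,
                        format(vm[["loss"]], digits = 4),
                        format(vm[["acc"]], digits = 3)))
      score <- if (is.na(vm[["acc"]])) ep_correct / n else vm[["acc"]]
      if (score > best$acc) best <- list(acc = score, net = net)
    }
  })
  list(net = best$net, history = do.call(rbind, hist))
}

#' Two-phase training
#'
#' Phase 1 trains all weights on the class-balanced patch set. Phase 2
#' refits only the output layer on patches with the natural (unbalanced)
#' class distribution, calibrating the class priors; every hidden weight
#' and normalization statistic is bit-identical before and after phase 2.
#' Hidden activations in phase 2 use the frozen inference-mode forward (no
#' dropout, frozen statistics), which is what makes the freeze exact.
#'
#' @param net An untrained `twopath_net`.
#' @param balanced Balanced training `patch_set` (phase 1).
#' @param natural `patch_set` preserving the source class distribution
#'   (phase 2); `NULL` skips phase 2.
#' @param cfg Phase-1 [train_config()].
#' @param val Optional validation set for phase 1.
#' @param phase2_cfg Phase-2 config; defaults to `cfg` with 5 epochs.
#' @param verbose Print per-epoch metrics.
#' @return List with `net`, `history` (phase 1) and `history2`.
#' @export
two_phase_train <- function(net, balanced, natural = NULL,
                            cfg = train_config(), val = NULL,
                            phase2_cfg = NULL, verbose = FALSE) {
  ph1 <- train_network(net, balanced, val, cfg, verbose = verbose)
  net <- ph1$net
  hist2 <- NULL
  if (!is.null(natural) && n_patches(natural) > 0) {
    if (is.null(phase2_cfg)) {
      phase2_cfg <- cfg
      phase2_cfg$epochs <- 5L
    }
    if (phase2_cfg$epochs > 0L) {
      ph2 <- train_output_layer(net, natural, phase2_cfg, verbose = verbose)
      net <- ph2$net
      hist2 <- ph2$history
    }
  }
  list(net = net, history = ph1$history, history2 = hist2)
}

# Phase 2: precompute the frozen concatenated feature maps of every patch
# (inference-mode hidden forward), then run RMSprop on the output
# convolution alone. Only net$params$conv_out changes.
train_output_layer <- function(net, ps, cfg, verbose = FALSE) {
  if (ps$channels != net$spec$input_channels)
    stop(sprintf("patch channels (%d) do not match network input channels (%d)",
                 ps$channels, net$spec$input_channels))
  n <- n_patches(ps)
  feats <- NULL
  chunk <- 256L
  for (at in seq(1L, n, by = chunk)) {
    idx <- at:min(n, at + chunk - 1L)
    f <- hidden_forward_eval(net, ps$patches[, , , idx, drop = FALSE])
    if (is.null(feats)) feats <- array(0, c(dim(f)[1:3], n))
    feats[, , , idx] <- f
  }
  y <- labels_to_onehot(ps$labels, net$spec$n_classes)
  state <- new_rms_state(net$params["conv_out"])
  hist <- list()
  with_seed(cfg$seed + 1L, {
    for (epoch in seq_len(cfg$epochs)) {
      ord <- sample.int(n)
      ep_loss <- 0
      for (at in seq(1L, n, by = cfg$batch_size)) {
        idx <- ord[at:min(n, at + cfg$batch_size - 1L)]
        xb <- feats[, , , idx, drop = FALSE]
        logits <- cpp_conv_forward(xb, net$params$conv_out$W,
                                   net$params$conv_out$b)
        pm <- matrix(softmax_channels(logits), net$spec$n_classes,
                     length(idx))
        py <- pm[cbind(ps$labels[idx] + 1L, seq_along(idx))]
        ep_loss <- ep_loss + sum(-log(pmax(py, 1e-12)))
        dl <- array((pm - y[, idx, drop = FALSE]) / length(idx),
                    c(1L, 1L, net$spec$n_classes, length(idx)))
        g <- cpp_conv_backward(xb, net$params$conv_out$W, dl)
        up <- rmsprop_update(net$params["conv_out"],
                             list(conv_out = list(W = g$dW, b = g$db)),
                             state, cfg)
        net$params$conv_out <- up$params$conv_out
        state <- up$state
      }
      hist[[epoch]] <- data.frame(epoch = epoch, train_loss = ep_loss / n)
      if (verbose)
        message(sprintf("phase-2 epoch %d: loss %.4f", epoch, ep_loss / n))
    }
  })
  list(net = net, history = do.call(rbind, hist))
}

# inference-mode forward up to (and including) the concatenation
hidden_forward_eval <- function(net, x) {
  x <- as_batch(x)
  s <- net$spec; p <- net$params; t <- s$norm_epsilon
  n1 <- norm_forward(relu(cpp_conv_forward(x, p$conv_l1$W, p$conv_l1$b)),
                     net$norm$l1, t, "eval")
  pl1 <- cpp_maxpool_forward(n1$out, s$pool_sizes[1])
  n2 <- norm_forward(relu(cpp_conv_forward(pl1$out, p$conv_l2$W, p$conv_l2$b)),
                     net$norm$l2, t, "eval")
  pl2 <- cpp_maxpool_forward(n2$out, s$pool_sizes[2])
  n3 <- norm_forward(relu(cpp_conv_forward(pl2$out, p$conv_l3$W, p$conv_l3$b)),
                     net$norm$l3, t, "eval")
  ng <- norm_forward(relu(cpp_conv_forward(x, p$conv_g$W, p$conv_g$b)),
                     net$norm$g, t, "eval")
  concat_channels(n3$out, ng$out)
}

#' Build the 7-channel cascade training set
#'
#' Runs the trained stage-1 network convolutionally over each 65x65 patch
#' (no padding), producing a 33x33x4 class-probability map, and
#' concatenates it with the co-centered 33x33x3 RGB patch into a 33x33x7
#' patch; labels carry over. The big and small sets must be center-aligned:
#' identical provenance order.
#'
#' @param stage1 Trained stage-1 `twopath_net` (3 input channels).
#' @param big `patch_set` of 65x65x3 patches.
#' @param small Co-centered `patch_set` of 33x33x3 patches.
#' @param chunk Patches per forward batch.
#' @return A `patch_set` of 33x33x7 patches.
#' @export
build_cascade_dataset <- function(stage1, big, small, chunk = 64L) {
  if (n_patches(big) != n_patches(small))
    stop("big and small patch sets differ in length")
  key <- c("frame", "row", "col", "flip")
  mism <- which(Reduce(`|`, lapply(key, function(k)
    big$provenance[[k]] != small$provenance[[k]])))
  if (length(mism))
    stop(sprintf("provenance misalignment between big and small sets at index %d",
                 mism[1]))
  n <- n_patches(small)
  out <- array(0, c(small$size, small$size, 3L + stage1$spec$n_classes, n))
  out[, , 1:3, ] <- small$patches
  for (at in seq(1L, n, by = chunk)) {
    idx <- at:min(n, at + chunk - 1L)
    pr <- net_forward(stage1, big$patches[, , , idx, drop = FALSE],
                      mode = "eval")$probs
    out[, , 3L + seq_len(stage1$spec$n_classes), idx] <- pr
  }
  new_patch_set(out, small$labels, small$provenance, small$size,
                3L + stage1$spec$n_classes)
}

#' A trained cascade pair
#' @param stage1 Stage-1 network (3 input channels, receptive field 33).
#' @param stage2 Stage-2 network (3 + n_classes input channels).
#' @return A `cascade_pair`.
#' @export
cascade_pair <- function(stage1, stage2) {
  stopifnot(inherits(stage1, "twopath_net"), inherits(stage2, "twopath_net"))
  if (stage2$spec$input_channels != 3L + stage1$spec$n_classes)
    stop("stage-2 input channels must equal 3 + n_classes")
  structure(list(stage1 = stage1, stage2 = stage2), class = "cascade_pair")
}

#' Train the full two-stage cascade
#'
#' Stage 1 is two-phase-trained on the 33-pixel patches; its dense output
#' on the co-centered 65-pixel patches builds the 7-channel cascade set, on
#' which stage 2 (same architecture except input channels) is two-phase
#' trained. The validation split is made once on the small set and the same
#' frames are used for the big/cascade sets.
#'
#' @param big Balanced 65x65x3 `patch_set`, center-aligned with `small`.
#' @param small Balanced 33x33x3 `patch_set`.
#' @param cfg A [train_config()].
#' @param spec Stage-1 [twopath_spec()] (input_channels 3).
#' @param natural_small,natural_big Optional unbalanced co-centered sets for
#'   phase-2 prior calibration.
#' @param val_fraction Validation fraction for the frame-level split.
#' @param phase2_cfg Optional phase-2 config.
#' @param verbose Print progress.
#' @return A `cascade_pair` with attached `history` attribute.
#' @export
train_cascade <- function(big, small, cfg = train_config(),
                          spec = twopath_spec(), natural_small = NULL,
                          natural_big = NULL, val_fraction = 1/6,
                          phase2_cfg = NULL, verbose = FALSE) {
  sp <- split_validation(small, val_fraction, seed = cfg$seed)
  in_val <- small$provenance$frame %in% sp$val_frames
  big_tr <- subset_patch_set(big, which(!in_val))
  big_va <- subset_patch_set(big, which(in_val))

  net1 <- build_network(spec, seed = cfg$seed)
  st1 <- two_phase_train(net1, sp$train, natural_small, cfg, val = sp$val,
                         phase2_cfg = phase2_cfg, verbose = verbose)

  casc_tr <- build_cascade_dataset(st1$net, big_tr, sp$train)
  casc_va <- build_cascade_dataset(st1$net, big_va, sp$val)
  casc_nat <- if (!is.null(natural_small) && !is.null(natural_big))
    build_cascade_dataset(st1$net, natural_big, natural_small) else NULL

  spec2 <- spec
  spec2$input_channels <- 3L + spec$n_classes
  net2 <- build_network(spec2, seed = cfg$seed + 1L)
  st2 <- two_phase_train(net2, casc_tr, casc_nat, cfg, val = casc_va,
                         phase2_cfg = phase2_cfg, verbose = verbose)

  pair <- cascade_pair(st1$net, st2$net)
  attr(pair, "history") <- list(stage1 = st1$history, stage1_phase2 = st1$history2,
                                stage2 = st2$history, stage2_phase2 = st2$history2)
  pair
}
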