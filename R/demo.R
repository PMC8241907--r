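# End-to-end phantom pipeline: phantom -> lumen/ROI -> patches -> cascade
# training -> dense cascade prediction on held-out frames -> metric report.

#' Configuration of the end-to-end phantom demo
#'
#' Bundles the phantom spec, patch extraction parameters, network
#' architecture, training configuration and inference/evaluation settings.
#' Defaults are desk-scale: the reduced phantom geometry, a slim network
#' (8/8/8 local and 16 global feature maps) and a few hundred patches per
#' class, sized so the whole pipeline runs in minutes on one CPU while
#' exercising every stage at full fidelity.
#'
#' @param phantom A [phantom_spec()].
#' @param small_size,big_size Patch sides of the two scales.
#' @param stride Patch grid stride for training extraction.
#' @param max_per_class_per_frame Extraction cap per class and frame.
#' @param natural_stride,natural_max Grid stride and total size of the
#'   unbalanced (natural-distribution) set used for phase-2 calibration.
#' @param spec Stage-1 [twopath_spec()].
#' @param train A [train_config()].
#' @param phase2_epochs Output-layer refit epochs (phase 2).
#' @param val_fraction Validation fraction of the frame-level split.
#' @param n_test_frames Held-out frames at the end of the pullback.
#' @param roi_depth ROI band depth in pixels.
#' @param min_area Small-region removal threshold, pixels.
#' @param colormap Colormap name for the RGB rendering.
#' @param intensity_scale Intensity mapped to 1.0 before color mapping.
#' @param seed Pipeline seed (patch subsampling; training seeds come from
#'   `train$seed`).
#' @return A `pipeline_config`.
#' @export
pipeline_config <- function(phantom = phantom_spec(),
                            small_size = 33L, big_size = 65L, stride = 3L,
                            max_per_class_per_frame = 36L,
                            natural_stride = 5L, natural_max = 700L,
                            spec = twopath_spec(maps_local = c(8L, 8L, 8L),
                                                maps_global = 16L,
                                                dropout_rate = 0.2),
                            train = train_config(learning_rate = 1e-3,
                                                 batch_size = 64L,
                                                 epochs = 6L, seed = 7L),
                            phase2_epochs = 3L, val_fraction = 1/6,
                            n_test_frames = 3L, roi_depth = 100L,
                            min_area = 32L, colormap = "sepia",
                            intensity_scale = 255, seed = 7L) {
  structure(as.list(environment()), class = "pipeline_config")
}

# co-centered companion of `ps` at another patch size, same provenance order
cocentered_set <- function(rgb_frames, ps, size) {
  n <- n_patches(ps)
  out <- array(0, c(size, size, 3L, n))
  for (f in unique(ps$provenance$frame)) {
    idx <- which(ps$provenance$frame == f)
    sub <- extract_patches_at(rgb_frames[[f]], size,
                              ps$provenance[idx, , drop = FALSE],
                              ps$labels[idx], frame_id = f)
    out[, , , idx] <- sub$patches
  }
  new_patch_set(out, ps$labels, ps$provenance, size, 3L)
}

#' Run the end-to-end phantom demo pipeline
#'
#' Generates a synthetic pullback, detects the guidewire band and per-frame
#' lumen contours, builds ROI masks, extracts and balances two-scale
#' patches from the training frames, trains the two-stage cascade with
#' two-phase training, predicts the held-out frames densely, post-processes
#' and evaluates against the phantom ground truth.
#'
#' @param cfg A [pipeline_config()].
#' @param out_dir Optional directory for report JSON, label maps and
#'   overlays.
#' @param verbose Print stage progress.
#' @return List with `metrics` (see [evaluate_segmentation()]), `pair`
#'   (trained `cascade_pair`), `history`, `lumen` (detected contours),
#'   `band`, `predictions` and `manifest` (seeds, config hash, versions).
#' @export
run_demo <- function(cfg = pipeline_config(), out_dir = NULL,
                     verbose = FALSE) {
  stopifnot(inherits(cfg, "pipeline_config"))
  say <- function(...) if (verbose) message(sprintf(...))

  say("stage phantom: %d frames", cfg$phantom$n_frames)
  ph <- generate_pullback(cfg$phantom)
  H <- cfg$phantom$depth_samples; W <- cfg$phantom$n_alines
  n_frames <- cfg$phantom$n_frames

  say("stage lumen/guidewire")
  band <- detect_guidewire(ph$frames)
  contours <- matrix(0L, n_frames, W)
  rois <- vector("list", n_frames)
  rgb <- vector("list", n_frames)
  for (f in seq_len(n_frames)) {
    gw <- guidewire_columns(band, f, W)
    contours[f, ] <- detect_lumen(ph$frames[[f]], guidewire_cols = gw)
    rois[[f]] <- build_roi(contours[f, ], H, gw, cfg$roi_depth)
    rgb[[f]] <- apply_colormap(pmin(ph$frames[[f]] / cfg$intensity_scale, 1),
                               cfg$colormap)
  }

  test_frames <- seq_len(n_frames) > n_frames - cfg$n_test_frames
  train_idx <- which(!test_frames)
  if (length(train_idx) < 2L) stop("stage patches: need at least 2 training frames")

  say("stage patches")
  small_sets <- lapply(train_idx, function(f)
    extract_patches(rgb[[f]], ph$labels[[f]], rois[[f]], cfg$small_size,
                    cfg$stride, frame_id = f,
                    max_per_class = cfg$max_per_class_per_frame,
                    seed = cfg$seed + f))
  small_all <- do.call(bind_patch_sets, small_sets)
  balanced_small <- balance_by_augmentation(small_all, seed = cfg$seed)
  balanced_big <- cocentered_set(rgb, balanced_small, cfg$big_size)

  nat_sets <- lapply(train_idx, function(f)
    extract_patches(rgb[[f]], ph$labels[[f]], rois[[f]], cfg$small_size,
                    cfg$natural_stride, frame_id = f))
  natural_small <- do.call(bind_patch_sets, nat_sets)
  if (n_patches(natural_small) > cfg$natural_max) {
    keep <- with_seed(cfg$seed + 1L,
                      sort(sample.int(n_patches(natural_small),
                                      cfg$natural_max)))
    natural_small <- subset_patch_set(natural_small, keep)
  }
  natural_big <- cocentered_set(rgb, natural_small, cfg$big_size)

  say("stage train: %d balanced / %d natural patches",
      n_patches(balanced_small), n_patches(natural_small))
  phase2_cfg <- cfg$train
  phase2_cfg$epochs <- cfg$phase2_epochs
  pair <- train_cascade(balanced_big, balanced_small, cfg$train,
                        spec = cfg$spec, natural_small = natural_small,
                        natural_big = natural_big,
                        val_fraction = cfg$val_fraction,
                        phase2_cfg = phase2_cfg, verbose = verbose)

  say("stage predict: %d held-out frames", sum(test_frames))
  preds <- list(); truths <- list(); regions <- list()
  for (f in which(test_frames)) {
    pr <- predict_cascade(pair, rgb[[f]], rois[[f]])
    lab <- remove_small_regions(pr$labels, cfg$min_area)
    preds[[length(preds) + 1L]] <- lab
    truths[[length(truths) + 1L]] <- ph$labels[[f]]
    regions[[length(regions) + 1L]] <- rois[[f]]
  }

  say("stage evaluate")
  metrics <- evaluate_segmentation(preds, truths, regions)

  manifest <- list(
    seed = cfg$seed, train_seed = cfg$train$seed,
    phantom_seed = cfg$phantom$seed,
    config_hash = rlang::hash(lapply(unclass(cfg), unclass)),
    package_version = as.character(utils::packageVersion("octplaque")))

  report <- list(metrics = metrics, pair = pair,
                 history = attr(pair, "history"), lumen = contours,
                 band = band, predictions = preds, manifest = manifest)

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    jsonlite::write_json(
      list(macro_f1 = metrics$summary$macro_f1,
           accuracy = metrics$summary$accuracy,
           per_image = metrics$per_image, manifest = manifest),
      file.path(out_dir, "report.json"), auto_unbox = TRUE, digits = NA)
    for (i in seq_along(preds)) {
      f <- which(test_frames)[i]
      write_label_map(preds[[i]],
                      file.path(out_dir, sprintf("pred_%03d.png", f)))
      png::writePNG(export_overlay(rgb[[f]], preds[[i]]),
                    file.path(out_dir, sprintf("overlay_%03d.png", f)))
    }
    write_contour_csv(contours, file.path(out_dir, "lumen_detected.csv"))
  }
  report
}
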