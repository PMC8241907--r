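# Per-class confusion accounting, precision / recall / accuracy, per-class
# and macro F1, per-image confidence intervals and paired Wilcoxon
# comparisons.

#' One-vs-rest confusion counts over an evaluated region
#'
#' For every class k, TP counts pixels of true class k predicted k, FP
#' pixels of other classes predicted k, FN pixels of class k predicted
#' otherwise, TN the rest; counts are restricted to `region` pixels and
#' each class's four counts sum to the evaluated pixel count.
#'
#' @param pred,truth Integer label maps of identical shape.
#' @param region Optional logical mask restricting the evaluation.
#' @return A `confusion_counts` data frame (class, tp, fp, tn, fn) with
#'   attribute `n` (evaluated pixel count).
#' @export
confusion <- function(pred, truth, region = NULL) {
  if (!all(dim(pred) == dim(truth)))
    stop("pred and truth shapes do not match")
  if (is.null(region)) region <- array(TRUE, dim(pred))
  if (!all(dim(region) == dim(pred)))
    stop("region shape does not match the label maps")
  p <- as.integer(pred[region])
  t <- as.integer(truth[region])
  n <- length(p)
  out <- data.frame(class = 0:3, tp = 0L, fp = 0L, tn = 0L, fn = 0L)
  for (k in 0:3) {
    tp <- sum(p == k & t == k)
    fp <- sum(p == k & t != k)
    fn <- sum(p != k & t == k)
    out[out$class == k, 2:5] <- c(tp, fp, n - tp - fp - fn, fn)
  }
  attr(out, "n") <- n
  class(out) <- c("confusion_counts", "data.frame")
  out
}

f1_score <- function(precision, recall) {
  ifelse(precision + recall == 0, 0,
         2 * precision * recall / (precision + recall))
}

#' Segmentation metrics from confusion counts
#'
#' Applies the standard formulas: precision = TP/(TP+FP), recall =
#' TP/(TP+FN), per-class one-vs-rest accuracy = (TP+TN)/n, per-class
#' F1 = 2 p r/(p+r); macro F1 averages F1 over the evaluated classes
#' (tissue classes 1-3 by default — background is excluded from the macro
#' average unless requested). Empty denominators are defined as 0 and
#' flagged; classes absent from the truth are flagged and skipped in the
#' macro average. Overall accuracy is the fraction of correctly labeled
#' evaluated pixels.
#'
#' @param cc A `confusion_counts`.
#' @param classes Classes entering the macro F1 (default 1:3).
#' @return A `metric_report` list: `per_class` data frame (class,
#'   precision, recall, f1, accuracy, flagged, present), `accuracy`,
#'   `macro_f1`.
#' @export
compute_metrics <- function(cc, classes = 1:3) {
  n <- attr(cc, "n")
  pc <- cc[cc$class %in% classes, , drop = FALSE]
  precision <- ifelse(pc$tp + pc$fp == 0, 0, pc$tp / (pc$tp + pc$fp))
  recall <- ifelse(pc$tp + pc$fn == 0, 0, pc$tp / (pc$tp + pc$fn))
  present <- pc$tp + pc$fn > 0
  per_class <- data.frame(
    class = pc$class,
    precision = precision,
    recall = recall,
    f1 = f1_score(precision, recall),
    accuracy = (pc$tp + pc$tn) / n,
    flagged = (pc$tp + pc$fp == 0) | (pc$tp + pc$fn == 0),
    present = present)
  macro <- if (any(present)) mean(per_class$f1[present]) else NA_real_
  structure(list(per_class = per_class,
                 accuracy = sum(cc$tp) / n,
                 macro_f1 = macro),
            class = "metric_report")
}

#' @export
print.metric_report <- function(x, ...) {
  cat(sprintf("accuracy %.4f, macro F1 %.4f\n", x$accuracy, x$macro_f1))
  print(x$per_class, row.names = FALSE)
  invisible(x)
}

#' Macro F1 from per-class precision/recall pairs
#'
#' Harmonic mean per pair, arithmetic mean over pairs; a pair with
#' precision + recall = 0 contributes 0.
#'
#' @param pr_pairs Two-column matrix or data frame (precision, recall),
#'   one row per class.
#' @return Macro F1.
#' @export
macro_f1_from_pr <- function(pr_pairs) {
  m <- as.matrix(pr_pairs)
  if (any(m < 0 | m > 1)) stop("precision/recall values must lie in [0, 1]")
  mean(f1_score(m[, 1], m[, 2]))
}

#' Mean and interval half-widths of a per-image metric
#'
#' Reports the mean together with both a normal-theory 95% confidence
#' half-width (1.96 * SD / sqrt(n)) and the sample SD, since published
#' "mean +/- x" intervals do not always state which of the two x is.
#'
#' @param values Per-image metric values (length >= 2).
#' @return List with `mean`, `sd`, `half_width_ci` and `n`.
#' @export
per_image_ci <- function(values) {
  n <- length(values)
  if (n < 2) stop("at least two per-image values are required")
  s <- sd(values)
  list(mean = mean(values), sd = s,
       half_width_ci = qnorm(0.975) * s / sqrt(n), n = n)
}

#' Paired Wilcoxon signed-rank comparison of per-image metrics
#'
#' Zero differences are discarded and ties mid-ranked; the null
#' distribution is exact for 15 or fewer non-zero differences and a normal
#' approximation with continuity correction above. If every difference is
#' zero the result is degenerate (statistic 0, p = 1) and flagged.
#'
#' @param a,b Paired per-image metric vectors of equal length >= 5.
#' @return List with `statistic` (V), `p_value`, `n_effective`,
#'   `degenerate`.
#' @export
wilcoxon_signed_rank <- function(a, b) {
  if (length(a) != length(b)) stop("a and b must be paired (equal length)")
  if (length(a) < 5) stop("at least 5 pairs are required")
  d <- a - b
  nz <- sum(d != 0)
  if (nz == 0)
    return(list(statistic = 0, p_value = 1, n_effective = 0L,
                degenerate = TRUE))
  wt <- suppressWarnings(wilcox.test(a, b, paired = TRUE,
                                     exact = nz <= 15, correct = TRUE))
  list(statistic = unname(wt$statistic), p_value = wt$p.value,
       n_effective = nz, degenerate = FALSE)
}

#' Evaluate predictions over a set of images
#'
#' Computes per-image metric reports, their across-image mean with interval
#' half-widths, and pooled (all pixels together) metrics.
#'
#' @param preds,truths Lists of label maps.
#' @param regions List of logical ROI masks (or NULL for whole images).
#' @param classes Classes entering macro F1.
#' @return List with `per_image` (data frame), `summary` (mean/sd/CI of
#'   macro F1 and accuracy) and `pooled` (`metric_report`).
#' @export
evaluate_segmentation <- function(preds, truths, regions = NULL,
                                  classes = 1:3) {
  stopifnot(length(preds) == length(truths))
  n <- length(preds)
  rows <- vector("list", n)
  pooled <- NULL
  for (i in seq_len(n)) {
    reg <- if (is.null(regions)) NULL else regions[[i]]
    cc <- confusion(preds[[i]], truths[[i]], reg)
    if (is.null(pooled)) pooled <- cc else {
      nn <- attr(pooled, "n") + attr(cc, "n")
      pooled[2:5] <- pooled[2:5] + cc[2:5]
      attr(pooled, "n") <- nn
    }
    m <- compute_metrics(cc, classes)
    rows[[i]] <- data.frame(image = i, macro_f1 = m$macro_f1,
                            accuracy = m$accuracy)
  }
  per_image <- do.call(rbind, rows)
  summary <- if (n >= 2)
    list(macro_f1 = per_image_ci(per_image$macro_f1),
         accuracy = per_image_ci(per_image$accuracy)) else NULL
  list(per_image = per_image, summary = summary,
       pooled = compute_metrics(pooled, classes))
}
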