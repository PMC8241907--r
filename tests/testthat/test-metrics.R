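# Confusion accounting, metric formulas, intervals, Wilcoxon comparisons.

test_that("perfect predictions give zero FP/FN and unit metrics", {
  set.seed(50)
  lm <- matrix(sample(0:3, 144, replace = TRUE), 12, 12)
  cc <- confusion(lm, lm)
  expect_true(all(cc$fp == 0))
  expect_true(all(cc$fn == 0))
  m <- compute_metrics(cc)
  expect_equal(m$accuracy, 1)
  expect_equal(m$macro_f1, 1)
  expect_true(all(m$per_class$precision == 1))
})

test_that("confusion counts equal an independent per-pixel tally", {
  set.seed(51)
  pred <- matrix(sample(0:3, 144, replace = TRUE), 12, 12)
  truth <- matrix(sample(0:3, 144, replace = TRUE), 12, 12)
  region <- matrix(sample(c(TRUE, FALSE), 144, replace = TRUE), 12, 12)
  cc <- confusion(pred, truth, region)
  n <- sum(region)
  for (k in 0:3) {
    tp <- fp <- fn <- tn <- 0L
    for (i in 1:12) for (j in 1:12) {
      if (!region[i, j]) next
      if (pred[i, j] == k && truth[i, j] == k) tp <- tp + 1L
      else if (pred[i, j] == k) fp <- fp + 1L
      else if (truth[i, j] == k) fn <- fn + 1L
      else tn <- tn + 1L
    }
    row <- cc[cc$class == k, ]
    expect_equal(unlist(row[2:5], use.names = FALSE), c(tp, fp, tn, fn))
    expect_equal(sum(row[2:5]), n)  # the four counts partition the region
  }
  expect_error(confusion(pred, truth[1:10, ]), "shapes")
})

test_that("a constant fibrous prediction splits a fibrous/lipid region", {
  truth <- matrix(c(rep(1L, 50), rep(3L, 50)), 10, 10)
  pred <- matrix(1L, 10, 10)
  cc <- confusion(pred, truth)
  expect_equal(cc$tp[cc$class == 1], 50L)
  expect_equal(cc$fn[cc$class == 3], 50L)
})

test_that("metric formulas are applied exactly, degenerate cases flagged", {
  # counts engineered to give precision .96 and recall .95 for class 1
  cc <- data.frame(class = 0:3,
                   tp = c(0L, 9120L, 0L, 0L),
                   fp = c(0L, 380L, 0L, 0L),
                   tn = c(20000L, 10020L, 20000L, 20000L),
                   fn = c(0L, 480L, 0L, 0L))
  attr(cc, "n") <- 20000L
  class(cc) <- c("confusion_counts", "data.frame")
  m <- compute_metrics(cc, classes = 1L)
  expect_equal(m$per_class$precision, 9120 / 9500)
  expect_equal(m$per_class$recall, 9120 / 9600)
  f1_oracle <- 2 * (9120 / 9500) * (9120 / 9600) /
    ((9120 / 9500) + (9120 / 9600))
  expect_equal(m$per_class$f1, f1_oracle)

  # empty denominators: defined as 0 and flagged
  cc0 <- confusion(matrix(0L, 4, 4), matrix(0L, 4, 4))
  m0 <- compute_metrics(cc0, classes = 2L)
  expect_equal(m0$per_class$precision, 0)
  expect_true(m0$per_class$flagged)
  expect_false(m0$per_class$present)
  expect_true(is.na(m0$macro_f1))
})

test_that("the printed macro F1 arises from the harmonic-arithmetic mean", {
  expect_equal(macro_f1_from_pr(rbind(c(1, 1), c(1, 1), c(1, 1))), 1)
  expect_equal(macro_f1_from_pr(rbind(c(0.96, 0.95))),
               2 * 0.96 * 0.95 / (0.96 + 0.95))
  expect_equal(macro_f1_from_pr(rbind(c(0, 0))), 0)  # empty pair -> 0
  expect_error(macro_f1_from_pr(rbind(c(1.2, 0.5))), "\\[0, 1\\]")
})

test_that("per-image intervals follow the hand formula and shrink with n", {
  ci <- per_image_ci(rep(0.7, 5))
  expect_equal(ci$mean, 0.7)
  expect_equal(ci$half_width_ci, 0)
  v <- c(0, 1)
  ci2 <- per_image_ci(v)
  expect_equal(ci2$mean, 0.5)
  expect_equal(ci2$half_width_ci, qnorm(0.975) * sd(v) / sqrt(2))
  # same spread, more images: narrower interval
  wide <- per_image_ci(rep(c(0, 1), 2))$half_width_ci
  narrow <- per_image_ci(rep(c(0, 1), 8))$half_width_ci
  expect_lt(narrow, wide)
  expect_error(per_image_ci(0.5), "two")
})

test_that("Wilcoxon handles degenerate, extreme and symmetric cases", {
  a <- c(0.8, 0.7, 0.9, 0.85, 0.75, 0.8, 0.9, 0.7, 0.6, 0.95)
  expect_error(wilcoxon_signed_rank(a, a[1:5]), "equal length")
  expect_error(wilcoxon_signed_rank(a[1:4], a[1:4]), "5 pairs")

  same <- wilcoxon_signed_rank(a, a)
  expect_true(same$degenerate)
  expect_equal(same$p_value, 1)

  # uniformly greater by large margins: exact two-sided p by enumeration
  b <- a - seq(0.1, 0.19, by = 0.01)
  res <- wilcoxon_signed_rank(a, b)
  n <- 10
  # enumerate all 2^n sign assignments of ranks 1..n
  ranks <- 1:n
  vs <- vapply(0:(2^n - 1), function(m)
    sum(ranks[bitwAnd(m, 2^(0:(n - 1))) > 0]), numeric(1))
  p_exact <- 2 * mean(vs >= res$statistic)
  expect_equal(res$statistic, n * (n + 1) / 2)
  expect_equal(res$p_value, p_exact)

  # exchanging the samples mirrors the statistic
  swap <- wilcoxon_signed_rank(b, a)
  expect_equal(swap$statistic, n * (n + 1) / 2 - res$statistic)
  expect_equal(swap$p_value, res$p_value)
})

test_that("evaluate_segmentation aggregates per-image and pooled metrics", {
  set.seed(52)
  truths <- replicate(3, matrix(sample(0:3, 100, replace = TRUE), 10, 10),
                      simplify = FALSE)
  preds <- lapply(truths, function(t) {
    p <- t
    flip <- sample(100, 15)
    p[flip] <- (p[flip] + 1L) %% 4L
    p
  })
  ev <- evaluate_segmentation(preds, truths)
  expect_equal(nrow(ev$per_image), 3)
  expect_true(all(ev$per_image$accuracy >= 0.8))
  expect_equal(ev$summary$accuracy$mean, mean(ev$per_image$accuracy))
  expect_equal(ev$pooled$accuracy, 1 - 45 / 300)
})
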