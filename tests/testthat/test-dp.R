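# Dynamic-programming boundary detection, guidewire band and ROI mask.

test_that("gradient cost is minimal exactly at a step edge", {
  frame <- matrix(0, 10, 6)
  frame[7:10, ] <- 1
  cost <- gradient_cost(frame)
  expect_equal(unname(apply(cost, 2, which.min)), rep(7L, 6))
  expect_true(all(gradient_cost(matrix(3, 5, 4)) == 0))
})

test_that("gradient cost equals an independent finite-difference table", {
  set.seed(2)
  f <- matrix(runif(8 * 6), 8, 6)
  cost <- gradient_cost(f)
  ref <- matrix(0, 8, 6)
  for (a in 1:6) for (d in 2:8) ref[d, a] <- -(f[d, a] - f[d - 1, a])
  expect_equal(cost, ref)
})

test_that("dp_min_path finds a zero-cost row and prefers smaller rows on ties", {
  cost <- matrix(1, 6, 8)
  cost[4, ] <- 0
  expect_equal(dp_min_path(cost, 2)$path, rep(4L, 8))
  # full tie: smallest row everywhere
  expect_equal(dp_min_path(matrix(1, 5, 5), 1)$path, rep(1L, 5))
})

test_that("dp_min_path is translation-equivariant", {
  set.seed(3)
  cost <- matrix(runif(7 * 9), 7, 9)
  p <- dp_min_path(cost, 2)$path
  # prepend an expensive row: the optimum shifts down by exactly one row
  p2 <- dp_min_path(rbind(10, cost), 2)$path
  expect_equal(p2, p + 1L)
})

test_that("dp_min_path matches exhaustive enumeration on small rasters", {
  set.seed(10)
  for (i in 1:8) {
    R <- sample(4:6, 1); C <- sample(4:6, 1)
    cost <- matrix(runif(R * C), R, C)
    s <- sample(1:2, 1)
    per <- i %% 2 == 0
    expect_equal(dp_min_path(cost, s, periodic = per)$total,
                 brute_force_dp(cost, s, periodic = per), tolerance = 1e-9)
  }
})

test_that("row wrap-around lets the path cross the angular seam", {
  cost <- matrix(1, 6, 3)
  cost[1, 1] <- 0; cost[6, 2] <- 0; cost[1, 3] <- 0
  res <- dp_min_path(cost, 1, wrap_rows = TRUE)
  expect_equal(res$path, c(1L, 6L, 1L))
  expect_equal(res$total, 0)
  # without wrap the seam jump is infeasible
  expect_gt(dp_min_path(cost, 1, wrap_rows = FALSE)$total, 0)
})

test_that("tripled periodic heuristic agrees with the exact method here", {
  set.seed(12)
  cost <- matrix(runif(8 * 12), 8, 12)
  ex <- dp_min_path(cost, 2, periodic = TRUE, method = "exact")
  tr <- dp_min_path(cost, 2, periodic = TRUE, method = "tripled")
  expect_lte(ex$total, tr$total + 1e-12)
  expect_lte(abs(tr$path[1] - tr$path[12]), 2)
})

test_that("lumen is recovered exactly on noise-free phantom frames", {
  ph <- noise_free_phantom()
  sp <- ph$spec
  for (f in seq_along(ph$frames)) {
    gw <- guidewire_columns(ph$guidewire_truth, f, sp$n_alines)
    ct <- detect_lumen(ph$frames[[f]], guidewire_cols = gw)
    non_gw <- setdiff(0:(sp$n_alines - 1), gw) + 1L
    expect_identical(ct[non_gw], ph$lumen_truth[f, non_gw])
    # interpolated guidewire columns stay within a pixel of the truth
    expect_lte(max(abs(ct - ph$lumen_truth[f, ])), 1)
    # closed contour
    expect_lte(abs(ct[1] - ct[sp$n_alines]), 2)
  }
})

test_that("a constant-radius lumen gives a constant contour", {
  sp <- phantom_spec(n_frames = 1L, lumen_wobble_amplitude = 0,
                     noise_sd = 0, guidewire_attenuation = 1, seed = 1L)
  ph <- generate_pullback(sp)
  ct <- detect_lumen(ph$frames[[1]])
  expect_true(all(ct == ct[1]))
})

test_that("lumen detection is intensity-scale invariant", {
  ph <- noise_free_phantom()
  a <- detect_lumen(ph$frames[[1]])
  b <- detect_lumen(ph$frames[[1]] * 3.7)
  expect_identical(a, b)
})

test_that("guidewire band is recovered within one A-line on the phantom", {
  sp <- phantom_spec(n_frames = 6L, seed = 33L)
  ph <- generate_pullback(sp)
  band <- detect_guidewire(ph$frames)
  W <- sp$n_alines
  d <- abs(band$center - ph$guidewire_truth$center)
  d <- pmin(d, W - d)
  expect_true(all(d <= 1))
  expect_lte(abs(band$half_width - ph$guidewire_truth$half_width), 2)
  expect_lt(band$detectability, 0.5)
})

test_that("single-frame detection reduces to the darkest-column neighborhood", {
  ph <- noise_free_phantom()
  band <- detect_guidewire(ph$frames[1])
  W <- ph$spec$n_alines
  d <- abs(band$center[1] - ph$guidewire_truth$center[1])
  expect_lte(min(d, W - d), 1)
})

test_that("a uniform pullback still returns a path, flagged undetectable", {
  frames <- list(matrix(1, 40, 30), matrix(1, 40, 30))
  band <- detect_guidewire(frames)
  expect_length(band$center, 2)
  expect_gte(band$detectability, 0.99)
  expect_equal(band$half_width, max(1L, round(0.05 * 30)))
})

test_that("ROI band geometry: 100-pixel depth, guidewire exclusion, clipping", {
  contour <- rep(50L, 40)
  roi <- build_roi(contour, 256L, roi_depth = 100L)
  expect_true(all(colSums(roi) == 100))
  expect_true(all(which(roi[, 1]) == 51:150))

  roi2 <- build_roi(contour, 256L, guidewire_cols = 10:20, roi_depth = 100L)
  expect_true(all(!roi2[, 11:21]))

  roi3 <- build_roi(rep(246L, 40), 256L, roi_depth = 100L)
  expect_true(all(colSums(roi3) == 10))

  expect_error(build_roi(contour, 256L, roi_depth = 0L), "positive")

  # area identity over non-guidewire columns
  set.seed(5)
  ct <- sample(150:250, 40, replace = TRUE)
  gw <- 3:7
  roi4 <- build_roi(ct, 256L, guidewire_cols = gw, roi_depth = 100L)
  expect_equal(sum(roi4),
               sum(pmin(100L, 256L - ct[-(gw + 1L)])))
})
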