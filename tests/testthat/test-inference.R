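# Dense inference, cascade prediction, masking, small-region removal.

test_that("dense inference equals sliding-window patch classification", {
  set.seed(40)
  img <- array(runif(44 * 36 * 3), c(44, 36, 3))
  net <- build_network(tiny_spec(), seed = 41L)
  dm <- predict_dense(net, img)
  expect_equal(dim(dm$probs), c(44L, 36L, 4L))
  padded <- octplaque:::pad_polar(img, 16L)
  for (k in 1:25) {
    r <- sample(44, 1); c <- sample(36, 1)
    patch <- padded[r:(r + 32), c:(c + 32), , drop = FALSE]
    dim(patch) <- c(33L, 33L, 3L)
    expect_equal(max(abs(predict_patches(net, patch) - dm$probs[r, c, ])),
                 0, tolerance = 1e-4)
  }
})

test_that("a constant image produces a constant probability map", {
  net <- build_network(tiny_spec(), seed = 42L)
  dm <- predict_dense(net, array(0.4, c(40, 40, 3)))
  for (k in 1:4)
    expect_lt(diff(range(dm$probs[, , k])), 1e-12)
})

test_that("unpadded inference requires the receptive field to fit", {
  net <- build_network(tiny_spec(), seed = 43L)
  expect_error(predict_dense(net, array(0.1, c(20, 20, 3)), pad = FALSE),
               "receptive field")
  # padded, a small image still works and stays pixel-aligned
  dm <- predict_dense(net, array(0.1, c(34, 33, 3)), pad = TRUE)
  expect_equal(dim(dm$probs)[1:2], c(34L, 33L))
})

test_that("cascade prediction masks everything outside the ROI as background", {
  set.seed(44)
  img <- array(runif(40 * 32 * 3), c(40, 32, 3))
  roi <- matrix(FALSE, 40, 32)
  roi[8:30, 4:28] <- TRUE
  pair <- cascade_pair(build_network(tiny_spec(), seed = 45L),
                       build_network(tiny_spec(input_channels = 7L), seed = 46L))
  pr <- predict_cascade(pair, img, roi)
  expect_true(all(pr$labels[!roi] == 0L))
  sums <- apply(pr$probs, c(1, 2), sum)
  expect_lt(max(abs(sums - 1)), 1e-9)
  # classes inside the ROI partition it
  expect_equal(sum(table(pr$labels[roi])), sum(roi))
})

test_that("cascade inference agrees with patch-by-patch cascade classification", {
  set.seed(47)
  img <- array(runif(100 * 40 * 3), c(100, 40, 3))
  pair <- cascade_pair(build_network(tiny_spec(), seed = 48L),
                       build_network(tiny_spec(input_channels = 7L), seed = 49L))
  pr <- predict_cascade(pair, img)
  pad16 <- octplaque:::pad_polar(img, 16L)
  pad32 <- octplaque:::pad_polar(img, 32L)
  for (k in 1:12) {
    r <- sample(33:67, 1)     # interior rows: single-reflection territory
    c <- sample(40, 1)
    big <- pad32[r:(r + 64), c:(c + 64), , drop = FALSE]
    dim(big) <- c(65L, 65L, 3L)
    m1 <- predict_dense(pair$stage1, big, pad = FALSE)$probs
    small7 <- array(0, c(33, 33, 7))
    small7[, , 1:3] <- pad16[r:(r + 32), c:(c + 32), ]
    small7[, , 4:7] <- m1
    oracle <- predict_patches(pair$stage2, small7)
    expect_equal(max(abs(oracle - pr$probs[r, c, ])), 0, tolerance = 1e-4)
  }
})

test_that("small isolated regions are absorbed by their surroundings", {
  lm <- matrix(1L, 12, 12)
  lm[5:6, 5] <- 2L; lm[7, 5] <- 2L           # 3-pixel calcified island
  out <- remove_small_regions(lm, min_area = 5L)
  expect_true(all(out == 1L))
  expect_identical(remove_small_regions(lm, 0L), lm)
})

test_that("only sub-threshold components are removed (flood-fill oracle)", {
  lm <- matrix(0L, 10, 10)
  lm[2:3, 2:3] <- 2L                        # area 4
  lm[6:9, 6:8] <- 3L                        # area 12
  out <- remove_small_regions(lm, 5L, wrap_cols = FALSE)
  # independent flood fill counting surviving non-background components
  flood_count <- function(m) {
    seen <- matrix(FALSE, nrow(m), ncol(m))
    n <- 0
    for (i in seq_len(nrow(m))) for (j in seq_len(ncol(m))) {
      if (seen[i, j] || m[i, j] == 0L) next
      n <- n + 1
      q <- list(c(i, j)); seen[i, j] <- TRUE
      while (length(q)) {
        p <- q[[1]]; q <- q[-1]
        for (d in list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))) {
          a <- p[1] + d[1]; b <- p[2] + d[2]
          if (a >= 1 && a <= nrow(m) && b >= 1 && b <= ncol(m) &&
              !seen[a, b] && m[a, b] == m[i, j]) {
            seen[a, b] <- TRUE
            q[[length(q) + 1]] <- c(a, b)
          }
        }
      }
    }
    n
  }
  expect_equal(flood_count(lm), 2L)
  expect_equal(flood_count(out), 1L)
  expect_true(all(out[6:9, 6:8] == 3L))
  expect_true(all(out[2:3, 2:3] == 0L))     # absorbed by background majority
  # idempotence at fixed threshold
  expect_identical(remove_small_regions(out, 5L, wrap_cols = FALSE), out)
})

test_that("components joined across the angular seam are measured as one", {
  lm <- matrix(0L, 8, 10)
  lm[3:5, c(1, 10)] <- 1L                   # 6 pixels, split by the seam
  expect_identical(remove_small_regions(lm, 5L, wrap_cols = TRUE), lm)
  out <- remove_small_regions(lm, 5L, wrap_cols = FALSE)
  expect_true(all(out == 0L))               # halves of 3 are each removed
})

test_that("absorption takes the majority neighbor class, background on ties", {
  # majority: island of 2 surrounded mostly by fibrous
  lm <- matrix(1L, 6, 9)
  lm[3, 4] <- 2L
  expect_equal(remove_small_regions(lm, 2L)[3, 4], 1L)
  # tie: two fibrous and two background neighbors
  lm2 <- matrix(0L, 6, 9)
  lm2[3, 4] <- 2L
  lm2[2, 4] <- 1L; lm2[4, 4] <- 1L
  out2 <- remove_small_regions(lm2, 2L)
  expect_equal(out2[3, 4], 0L)
})
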