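# Training dynamics, two-phase freeze, cascade dataset construction.

test_that("a separable bright/dark problem is learned within 5 epochs", {
  train <- make_patch_set(c(60L, 60L), seed = 1L)
  val <- make_patch_set(c(20L, 20L), seed = 2L)
  net <- build_network(tiny_spec(), seed = 3L)
  cfg <- train_config(learning_rate = 1e-3, batch_size = 32L, epochs = 5L,
                      seed = 4L)
  res <- train_network(net, train, val, cfg)
  expect_gte(max(res$history$val_acc), 0.95)
})

test_that("zero learning rate leaves every weight unchanged", {
  train <- make_patch_set(c(10L, 10L), seed = 5L)
  net <- build_network(tiny_spec(), seed = 6L)
  cfg <- train_config(learning_rate = 0, batch_size = 8L, epochs = 1L)
  res <- train_network(net, train, NULL, cfg)
  expect_identical(res$net$params, net$params)
})

test_that("training is reproducible under a fixed seed", {
  train <- make_patch_set(c(15L, 15L), seed = 7L)
  val <- make_patch_set(c(8L, 8L), seed = 8L)
  cfg <- train_config(learning_rate = 5e-4, batch_size = 16L, epochs = 2L,
                      seed = 9L)
  r1 <- train_network(build_network(tiny_spec(), seed = 10L), train, val, cfg)
  r2 <- train_network(build_network(tiny_spec(), seed = 10L), train, val, cfg)
  expect_identical(r1$history, r2$history)
  expect_identical(r1$net$params, r2$net$params)
})

test_that("channel mismatches abort before training", {
  train <- make_patch_set(c(5L, 5L), channels = 7L)
  net <- build_network(tiny_spec(), seed = 1L)
  expect_error(train_network(net, train, NULL, train_config()), "channels")
})

test_that("phase 2 freezes every non-output weight bit-exactly", {
  balanced <- make_patch_set(c(20L, 20L, 20L), seed = 11L)
  natural <- make_patch_set(c(40L, 6L, 6L), seed = 12L)
  net <- build_network(tiny_spec(), seed = 13L)
  cfg <- train_config(learning_rate = 1e-3, batch_size = 16L, epochs = 2L,
                      seed = 14L)
  ph1 <- train_network(net, balanced, NULL, cfg)
  res <- two_phase_train(net, balanced, natural, cfg)
  for (nm in c("conv_l1", "conv_l2", "conv_l3", "conv_g"))
    expect_identical(res$net$params[[nm]], ph1$net$params[[nm]])
  expect_false(identical(res$net$params$conv_out, ph1$net$params$conv_out))
  expect_identical(res$net$norm, ph1$net$norm)
})

test_that("zero phase-2 epochs leave the network unchanged", {
  balanced <- make_patch_set(c(10L, 10L), seed = 15L)
  natural <- make_patch_set(c(10L, 2L), seed = 16L)
  net <- build_network(tiny_spec(), seed = 17L)
  cfg <- train_config(learning_rate = 1e-3, batch_size = 8L, epochs = 1L)
  p2 <- cfg; p2$epochs <- 0L
  a <- two_phase_train(net, balanced, natural, cfg, phase2_cfg = p2)
  b <- train_network(net, balanced, NULL, cfg)
  expect_identical(a$net$params, b$net$params)
})

test_that("phase 2 on class-0-dominated data raises the class-0 prior", {
  balanced <- make_patch_set(c(25L, 25L), seed = 18L)
  natural <- make_patch_set(c(60L, 4L), seed = 19L)
  net <- build_network(tiny_spec(), seed = 20L)
  cfg <- train_config(learning_rate = 1e-3, batch_size = 16L, epochs = 2L,
                      seed = 21L)
  ph1 <- train_network(net, balanced, NULL, cfg)
  res <- two_phase_train(net, balanced, natural, cfg)
  # prior calibration: the mean predicted class-0 probability on held-out
  # patches drawn from the same skewed mixture must increase
  hold <- make_patch_set(c(30L, 2L), seed = 77L)
  before <- mean(predict_patches(ph1$net, hold$patches)[, 1])
  after <- mean(predict_patches(res$net, hold$patches)[, 1])
  expect_gt(after, before)
})

test_that("the cascade dataset has 7 conserved probability channels", {
  small <- make_patch_set(c(6L, 6L), size = 33L, seed = 22L)
  big <- make_patch_set(c(6L, 6L), size = 65L, seed = 22L)
  big$provenance <- small$provenance  # co-centered by construction here
  stage1 <- build_network(tiny_spec(), seed = 23L)
  casc <- build_cascade_dataset(stage1, big, small)
  expect_equal(casc$channels, 7L)
  expect_equal(dim(casc$patches)[1:3], c(33L, 33L, 7L))
  sums <- apply(casc$patches[, , 4:7, ], c(1, 2, 4), sum)
  expect_lt(max(abs(sums - 1)), 1e-9)
  expect_identical(casc$labels, small$labels)
  # RGB channels carried over untouched
  expect_identical(casc$patches[, , 1:3, ], small$patches[, , , ])
})

test_that("the cascade center probabilities equal the patch-forward oracle", {
  small <- make_patch_set(c(4L, 4L), size = 33L, seed = 24L)
  big <- make_patch_set(c(4L, 4L), size = 65L, seed = 24L)
  big$provenance <- small$provenance
  stage1 <- build_network(tiny_spec(), seed = 25L)
  casc <- build_cascade_dataset(stage1, big, small)
  for (i in c(1L, 5L)) {
    crop <- big$patches[17:49, 17:49, , i, drop = FALSE]
    dim(crop) <- c(33L, 33L, 3L)
    pr <- predict_patches(stage1, crop)
    expect_equal(casc$patches[17, 17, 4:7, i], pr[1, ], tolerance = 1e-9)
  }
})

test_that("provenance misalignment is reported with its index", {
  small <- make_patch_set(c(4L, 4L), size = 33L, seed = 26L)
  big <- make_patch_set(c(4L, 4L), size = 65L, seed = 26L)
  big$provenance <- small$provenance
  big$provenance$row[3] <- big$provenance$row[3] + 1L
  stage1 <- build_network(tiny_spec(), seed = 27L)
  expect_error(build_cascade_dataset(stage1, big, small), "index 3")
})

test_that("training on uniform-random labels cannot beat the entropy floor", {
  set.seed(28)
  train <- make_patch_set(c(50L, 50L, 50L, 50L), seed = 29L,
                          means = rep(0.5, 4))       # no class signal
  val <- make_patch_set(c(15L, 15L, 15L, 15L), seed = 30L,
                        means = rep(0.5, 4))
  net <- build_network(tiny_spec(), seed = 31L)
  cfg <- train_config(learning_rate = 1e-3, batch_size = 32L, epochs = 2L,
                      seed = 32L)
  res <- train_network(net, train, val, cfg)
  expect_gte(min(res$history$val_loss), log(4) - 0.12)
})
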