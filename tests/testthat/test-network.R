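expected_trace <- data.frame(
  level = c(1L, 1L, 2L, 2L, 3L, 4L, 4L, 4L, 5L, 5L, 5L, 6L),
  operator = c("Encoder block 1", "Maxpooling layer 1", "Encoder block 2",
               "Maxpooling layer 2", "Pyramidal attention block",
               "Upsampling layer 1", "Concatenation", "Decoder block 1",
               "Upsampling layer 2", "Concatenation", "Decoder block 2",
               "Convolutional layer (1 x 1)"),
  height = c(64L, 32L, 32L, 16L, 16L, 32L, 32L, 32L, 64L, 64L, 64L, 64L),
  width = c(64L, 32L, 32L, 16L, 16L, 32L, 32L, 32L, 64L, 64L, 64L, 64L),
  channels = c(32L, 32L, 64L, 64L, 64L, 64L, 128L, 64L, 32L, 64L, 32L, 1L),
  stringsAsFactors = FALSE)

test_that("the default network reproduces the published feature-map table", {
  net <- build_segnet()
  expect_identical(trace_shapes(net), expected_trace)
})

test_that("default parameter count is 891,713, seed- and data-independent", {
  net <- build_segnet(seed = 1)
  expect_identical(count_trainable_parameters(net), 891713)
  # closed-form count over the graph agrees with the engine's own count
  expect_identical(noduleseg:::.g_count_params(net$graph), 891713)
  net2 <- build_segnet(seed = 999)
  expect_identical(count_trainable_parameters(net2), 891713)
  invisible(forward(net2, matrix(0.5, 64, 64)))
  expect_identical(count_trainable_parameters(net2), 891713)
})

test_that("forward passes are in (0,1), deterministic, and batch-consistent", {
  net <- build_segnet(seed = 4)
  z <- forward(net, matrix(0, 64, 64))
  expect_identical(dim(z), c(64L, 64L))
  expect_true(all(z > 0 & z < 1))
  set.seed(10)
  x <- matrix(runif(64 * 64), 64, 64)
  expect_identical(forward(net, x), forward(net, x))
  # batched inference equals per-sample inference
  xs <- array(runif(64 * 64 * 4), c(64, 64, 1, 4))
  batched <- forward(net, xs, drop = FALSE)
  for (i in 1:4)
    expect_lt(max(abs(batched[, , 1, i] - forward(net, xs[, , 1, i]))), 1e-5)
  expect_error(forward(net, matrix(0, 32, 32)), "does not match")
})

test_that("two networks built with the same seed are identical", {
  a <- build_segnet(seed = 77); b <- build_segnet(seed = 77)
  set.seed(3)
  x <- matrix(runif(64 * 64), 64, 64)
  expect_identical(forward(a, x), forward(b, x))
})

test_that("binarize thresholds correctly and validates its inputs", {
  m <- matrix(0.6, 4, 4)
  expect_true(all(binarize(m, 0.5) == 1))
  expect_true(all(binarize(m, 0.0) == 1))
  expect_identical(binarize(0.5, 0.5), 1L)     # >= convention at the boundary
  expect_error(binarize(m, 1.1), "\\[0, 1\\]")
  expect_error(binarize(m, -0.1), "\\[0, 1\\]")
  # fraction of foreground is non-increasing in the threshold
  set.seed(4)
  pm <- matrix(runif(400), 20, 20)
  fracs <- sapply(seq(0, 1, by = 0.1), function(t) mean(binarize(pm, t)))
  expect_true(all(diff(fracs) <= 0))
})

test_that("the U-Net baseline has the right shape and a far larger budget", {
  un <- build_unet(depth = 2, base_filters = 8, input_size = 32)
  out <- forward(un, matrix(0.5, 32, 32))
  expect_identical(dim(out), c(32L, 32L))
  expect_true(all(out > 0 & out < 1))
  # classic depth-4/64-filter U-Net dwarfs the pyramid-attention network
  segnet_params <- count_trainable_parameters(build_segnet())
  expect_gt(count_trainable_parameters(build_unet(4, 64)), segnet_params)
  expect_gt(count_trainable_parameters(build_unet(3, 32)), segnet_params)
  expect_error(build_unet(depth = 5, input_size = 48), "divisible")
})

test_that("the U-Net baseline trains: loss drops below its starting value", {
  samples <- synth_dataset(10, seed = 41)
  un <- build_unet(depth = 2, base_filters = 8, seed = 6)
  fit <- train(un, samples, train_config(batch_size = 10, epochs = 50,
                                         val_fraction = 0, seed = 2))
  expect_identical(nrow(fit$log), 50L)
  expect_lt(fit$log$train_loss[50], fit$log$train_loss[1])
})

test_that("weight checkpointing round-trips through a rebuilt network", {
  net <- build_segnet(seed = 12)
  w <- net_weights(net)
  net2 <- build_segnet(seed = 999)
  set_net_weights(net2, w)
  set.seed(5)
  x <- matrix(runif(64 * 64), 64, 64)
  expect_identical(forward(net, x), forward(net2, x))
  w_bad <- w
  w_bad[[2]]$W <- w_bad[[2]]$W[, -1, drop = FALSE]
  expect_error(set_net_weights(net2, w_bad), "mismatch")
})
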