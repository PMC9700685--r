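# Squeeze-excitation and inverted-residual block behaviour, probed through
# single-block networks with direct weight surgery.

test_that("a saturated squeeze-excitation gate is the identity", {
  set.seed(1)
  fm <- array(runif(8 * 8 * 6), c(8, 8, 6))
  net <- se_network(6, ratio = 0.5, height = 8, width = 8, bias = TRUE)
  w <- net_weights(net)
  # zero the second dense layer and push its bias deep into saturation
  gate_node <- max(which(vapply(w, function(x) !is.null(x$W), TRUE)))
  w[[gate_node]]$W[] <- 0
  w[[gate_node]]$b[] <- 30            # sigmoid(30) = 1 - 9e-14
  out <- squeeze_excite(fm, 0.5, weights = w)
  expect_lt(max(abs(out - fm)), 1e-6)
})

test_that("zero input with zero biases gives zero output", {
  fm <- array(0, c(8, 8, 4))
  out <- squeeze_excite(fm, 0.25, seed = 4)
  expect_true(all(out == 0))
})

test_that("each output channel is one scalar in (0,1) times its input channel", {
  set.seed(2)
  fm <- array(rnorm(16 * 16 * 8), c(16, 16, 8))
  out <- squeeze_excite(fm, 0.25, seed = 11)
  for (c in 1:8) {
    ratio <- out[, , c] / fm[, , c]
    expect_lt(diff(range(ratio)), 1e-6)       # constant per channel
    expect_gt(mean(ratio), 0)
    expect_lt(mean(ratio), 1)
  }
})

test_that("squeeze-excitation matches an independent R computation", {
  set.seed(3)
  fm <- array(rnorm(8 * 8 * 5), c(8, 8, 5))
  net <- se_network(5, ratio = 0.4, height = 8, width = 8)
  w <- net_weights(net)
  nodes <- which(vapply(w, function(x) !is.null(x$W), TRUE))
  w1 <- w[[nodes[1]]]; w2 <- w[[nodes[2]]]
  z <- apply(fm, 3, mean)
  h <- as.numeric(w1$W %*% z + w1$b)
  h <- h * plogis(h)                           # swish bottleneck
  gate <- plogis(as.numeric(w2$W %*% h + w2$b))
  expected <- sweep(fm, 3, gate, `*`)
  expect_lt(max(abs(forward(net, fm) - expected)), 1e-10)
})

test_that("the residual skip is present exactly when channels match", {
  cfg <- ir_block_config(12, 12, expansion = 4)
  net <- ir_network(cfg, 8, 8)
  w <- net_weights(net)
  for (i in seq_along(w)) {            # zero every weight, bias, gamma, beta
    for (f in c("W", "b", "gamma", "beta"))
      if (!is.null(w[[i]][[f]])) w[[i]][[f]][] <- 0
  }
  set_net_weights(net, w)
  set.seed(5)
  fm <- array(rnorm(8 * 8 * 12), c(8, 8, 12))
  expect_lt(max(abs(forward(net, fm) - fm)), 1e-12)   # pure skip survives

  cfg2 <- ir_block_config(3, 16, expansion = 4)
  net2 <- ir_network(cfg2, 8, 8)
  w2 <- net_weights(net2)
  for (i in seq_along(w2))
    for (f in c("W", "b", "gamma", "beta"))
      if (!is.null(w2[[i]][[f]])) w2[[i]][[f]][] <- 0
  set_net_weights(net2, w2)
  fm2 <- array(rnorm(8 * 8 * 3), c(8, 8, 3))
  out2 <- forward(net2, fm2)
  expect_identical(dim(out2), c(8L, 8L, 16L))
  expect_true(all(out2 == 0))                          # no skip possible
})

test_that("block output shape is (H, W, filters) across input sizes", {
  cfg <- ir_block_config(4, 10, expansion = 3)
  for (hw in c(8L, 16L, 32L, 64L)) {
    fm <- array(rnorm(hw * hw * 4), c(hw, hw, 4))
    expect_identical(dim(inverted_residual(fm, cfg, seed = 2)),
                     c(hw, hw, 10L))
  }
})

test_that("engine parameter count matches the closed-form stage arithmetic", {
  for (cfg in list(c(64, 64, 4), c(32, 64, 4), c(16, 16, 6), c(1, 32, 4))) {
    net <- ir_network(ir_block_config(cfg[1], cfg[2], expansion = cfg[3]),
                      8, 8)
    expect_identical(count_trainable_parameters(net),
                     ir_params_closed_form(cfg[1], cfg[2], cfg[3]))
  }
})

test_that("channel mismatches and bad configs are rejected", {
  cfg <- ir_block_config(8, 8)
  fm <- array(0, c(8, 8, 5))
  expect_error(inverted_residual(fm, cfg), "channels")
  expect_error(ir_block_config(8, 8, kernel = 4), "kernel")
  expect_error(ir_block_config(8, 8, stride = 2), "stride 1")
})
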