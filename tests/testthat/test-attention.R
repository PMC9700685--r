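test_that("the bridge preserves shape for admissible inputs", {
  set.seed(1)
  fm <- array(rnorm(16 * 16 * 64), c(16, 16, 64))
  out <- feature_pyramid_attention(fm, seed = 3)
  expect_identical(dim(out), dim(fm))
  # a non-default width/channel combination
  cfg <- pyramid_config(channels = 8L, width = 12L)
  fm2 <- array(rnorm(32 * 24 * 8), c(32, 24, 8))
  expect_identical(dim(feature_pyramid_attention(fm2, cfg, seed = 4)), dim(fm2))
})

test_that("every pyramid level halves the spatial dims", {
  net <- fpa_network(pyramid_config(channels = 16L, width = 8L), 16, 16)
  pools <- Filter(function(n) n$op == "maxpool", net$graph)
  expect_identical(vapply(pools, function(n) n$H, integer(1)), c(8L, 4L, 2L))
  ups <- Filter(function(n) n$op == "upsample", net$graph)
  expect_identical(sort(vapply(ups, function(n) n$H, integer(1))), c(4L, 8L, 16L))
})

test_that("an all-ones attention map reduces the block to its main branch", {
  set.seed(2)
  cfg <- pyramid_config(channels = 6L, width = 4L, bias = TRUE)
  fm <- array(rnorm(16 * 16 * 6), c(16, 16, 6))
  net <- fpa_network(cfg, 16, 16)
  w <- net_weights(net)
  convs <- which(vapply(w, function(x) !is.null(x$W), TRUE))
  gate <- convs[length(convs)]               # final 1x1 projection
  w[[gate]]$W[] <- 0
  w[[gate]]$b[] <- 1
  set_net_weights(net, w)
  expect_lt(max(abs(forward(net, fm) - fm)), 1e-12)

  # with a main-branch 1x1 conv, the result is exactly that convolution
  cfgm <- pyramid_config(channels = 6L, width = 4L, bias = TRUE,
                         main_conv = TRUE)
  netm <- fpa_network(cfgm, 16, 16)
  wm <- net_weights(netm)
  convsm <- which(vapply(wm, function(x) !is.null(x$W), TRUE))
  # the gate projection feeds the mul; the main conv is the other 1x1
  km <- vapply(netm$graph[convsm], function(n) n$k, integer(1))
  onebyones <- convsm[km == 1]
  gate_m <- onebyones[1]                      # projection comes first
  main_m <- onebyones[2]
  wm[[gate_m]]$W[] <- 0; wm[[gate_m]]$b[] <- 1
  set_net_weights(netm, wm)
  Wmain <- wm[[main_m]]$W; bmain <- as.numeric(wm[[main_m]]$b)
  flat <- matrix(aperm(fm, c(3, 1, 2)), nrow = 6)
  expected <- aperm(array(as.numeric(Wmain %*% flat) + bmain, c(6, 16, 16)),
                    c(2, 3, 1))
  expect_lt(max(abs(forward(netm, fm) - expected)), 1e-10)
})

test_that("zero input with zero biases maps to zero output", {
  fm <- array(0, c(16, 16, 64))
  out <- feature_pyramid_attention(fm, seed = 9)   # default: bias-free convs
  expect_true(all(out == 0))
})

test_that("inadmissible inputs are rejected", {
  cfg <- pyramid_config(channels = 4L, width = 4L)
  expect_error(feature_pyramid_attention(array(0, c(12, 12, 4)), cfg),
               "divisible")
  expect_error(feature_pyramid_attention(array(0, c(16, 16, 5)), cfg),
               "channels")
  expect_error(pyramid_config(kernel_sizes = c(3, 5, 7)))
  expect_error(pyramid_config(kernel_sizes = c(7, 4, 3)))
})

test_that("outputs and gradients through the bridge stay finite", {
  set.seed(6)
  g <- noduleseg:::.g_new()
  i <- noduleseg:::.g_input(g, 8, 8, 4)
  b <- noduleseg:::.g_fpa(g, i, pyramid_config(c(5, 3), channels = 4L,
                                               width = 6L))
  h <- noduleseg:::.g_conv(g, b, 1L, 1L, bias = TRUE)
  noduleseg:::.g_act(g, h, "sigmoid")
  net <- noduleseg:::.net_new(g, seed = 8, "double", "fpa_grad")
  x <- array(runif(8 * 8 * 4 * 2), c(8, 8, 4, 2))
  y <- array(rbinom(8 * 8 * 2, 1, 0.5), c(8, 8, 1, 2))
  expect_true(all(is.finite(forward(net, x, drop = FALSE))))
  gr <- noduleseg:::eng_grad(net$ptr, x, y)
  for (gi in gr)
    for (f in c("dW", "db", "dgamma", "dbeta"))
      if (!is.null(gi[[f]])) expect_true(all(is.finite(gi[[f]])))
})
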