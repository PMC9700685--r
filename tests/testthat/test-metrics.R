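# hand-built 8x8 pair with |G| = 4, |P| = 6, |G & P| = 3
toy_pair <- local({
  gt <- matrix(0L, 8, 8); pred <- matrix(0L, 8, 8)
  gt[2, 2:5] <- 1L                 # 4 px
  pred[2, 3:5] <- 1L               # 3 overlapping
  pred[5, 1:3] <- 1L               # 3 disjoint
  list(gt = gt, pred = pred)
})

test_that("the four metrics match pixel counting on the toy pair", {
  expect_equal(dsc(toy_pair$gt, toy_pair$pred), 0.6)
  expect_equal(iou(toy_pair$gt, toy_pair$pred), 3 / 7)
  expect_equal(sensitivity(toy_pair$gt, toy_pair$pred), 0.75)
  expect_equal(precision(toy_pair$gt, toy_pair$pred), 0.5)
  m <- seg_metrics(toy_pair$gt, toy_pair$pred)
  expect_identical(c(m$n_gt, m$n_pred, m$n_intersection), c(4L, 6L, 3L))
})

test_that("identical, disjoint and subset masks hit the boundary values", {
  g <- matrix(0L, 6, 6); g[2:4, 2:4] <- 1L
  expect_equal(dsc(g, g), 1)
  expect_equal(iou(g, g), 1)
  d <- matrix(0L, 6, 6); d[6, 6] <- 1L
  expect_equal(dsc(g, d), 0)
  sub <- matrix(0L, 6, 6); sub[2, 2] <- 1L
  expect_equal(precision(g, sub), 1)            # pred subset of gt
  expect_equal(sensitivity(g, matrix(1L, 6, 6)), 1)  # pred covers everything
})

test_that("degenerate-mask conventions are as documented", {
  e <- matrix(0L, 4, 4)
  g <- matrix(0L, 4, 4); g[1, 1] <- 1L
  # both empty -> 1 everywhere
  for (f in list(dsc, iou, sensitivity, precision)) expect_equal(f(e, e), 1)
  # empty prediction, non-empty gt -> 0 (sensitivity included)
  expect_equal(dsc(g, e), 0)
  expect_equal(iou(g, e), 0)
  expect_equal(sensitivity(g, e), 0)
  expect_equal(precision(g, e), 0)
  # empty gt, non-empty prediction
  expect_equal(sensitivity(e, g), 1)
  expect_equal(precision(e, g), 0)
})

test_that("metrics agree with brute-force counting on 1000 random pairs", {
  set.seed(42)
  for (i in 1:1000) {
    g <- random_mask(12, 12, runif(1, 0.05, 0.6))
    p <- random_mask(12, 12, runif(1, 0.05, 0.6))
    k <- bf_counts(g, p)
    expect_identical(dsc(g, p),
                     if (k$ng + k$np == 0) 1 else 2 * k$ni / (k$ng + k$np))
    expect_identical(iou(g, p),
                     if (k$ng + k$np - k$ni == 0) 1 else k$ni / (k$ng + k$np - k$ni))
    d <- dsc(g, p); j <- iou(g, p)
    expect_lte(j, d + 1e-15)                       # IoU never exceeds Dice
    expect_equal(d, 2 * j / (1 + j), tolerance = 1e-12)
    if (k$ni > 0) {
      s <- sensitivity(g, p); pr <- precision(g, p)
      expect_equal(d, 2 * s * pr / (s + pr), tolerance = 1e-12)
    }
  }
})

test_that("symmetries: dsc/iou symmetric, sensitivity and precision swap", {
  set.seed(7)
  for (i in 1:50) {
    g <- random_mask(10, 10, 0.3); p <- random_mask(10, 10, 0.3)
    expect_identical(dsc(g, p), dsc(p, g))
    expect_identical(iou(g, p), iou(p, g))
    expect_identical(sensitivity(g, p), precision(p, g))
    expect_identical(precision(g, p), sensitivity(p, g))
  }
})

test_that("metrics are invariant under a joint pixel permutation", {
  set.seed(8)
  g <- random_mask(9, 9, 0.4); p <- random_mask(9, 9, 0.4)
  perm <- sample(81)
  gp <- matrix(g[perm], 9, 9); pp <- matrix(p[perm], 9, 9)
  expect_identical(seg_metrics(g, p)[1:4], seg_metrics(gp, pp)[1:4])
})

test_that("shape or value violations are rejected", {
  expect_error(dsc(matrix(0, 2, 2), matrix(0, 3, 3)), "identical shape")
  expect_error(iou(matrix(2, 2, 2), matrix(0, 2, 2)), "binary")
})

test_that("batch_report aggregates macro and micro correctly", {
  g <- matrix(0L, 6, 6); g[2:4, 2:4] <- 1L
  one <- batch_report(list(g), list(g))
  expect_equal(one$macro$dsc, 1)
  expect_equal(one$micro$dsc, 1)
  # n identical pairs equal the single-pair metrics
  rep5 <- batch_report(rep(list(toy_pair$gt), 5), rep(list(toy_pair$pred), 5))
  expect_equal(rep5$macro$dsc, 0.6)
  expect_equal(rep5$micro$dsc, 0.6)
  # macro average of dsc {1, 0} is 0.5
  d <- matrix(0L, 6, 6); d[6, 6] <- 1L
  mix <- batch_report(list(g, g), list(g, d))
  expect_equal(mix$macro$dsc, 0.5)
  # micro equals metrics of pooled counts (oracle by brute force)
  k1 <- bf_counts(g, g); k2 <- bf_counts(g, d)
  expect_equal(mix$micro$dsc,
               2 * (k1$ni + k2$ni) / (k1$ng + k2$ng + k1$np + k2$np))
  expect_error(batch_report(list(), list()), "empty")
})

test_that("reports round-trip to CSV and JSON", {
  rep <- batch_report(list(toy_pair$gt), list(toy_pair$pred), ids = "t1")
  path <- file.path(tempdir(), "rep")
  write_report(rep, path)
  per <- read.csv(paste0(path, ".csv"))
  expect_equal(per$dsc, 0.6)
  js <- jsonlite::read_json(paste0(path, ".json"))
  expect_equal(js$macro$dsc, 0.6)
})
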