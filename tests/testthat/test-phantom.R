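test_that("disk masks are exact Euclidean lattice disks", {
  # radius 5 at the center: 81 lattice points with x^2 + y^2 <= 25
  # (brute-force oracle over the offset grid)
  oracle <- sum(outer((-8):8, (-8):8,
                      function(x, y) x^2 + y^2 <= 25))
  expect_identical(oracle, 81L)
  p <- synth_patch(nodule_spec(radius_px = 5, center = c(32, 32), noise_sd = 0))
  expect_identical(sum(p$mask), 81L)
  # sub-pixel radius keeps only the center pixel
  p04 <- synth_patch(nodule_spec(radius_px = 0.4, center = c(32, 32)))
  expect_identical(sum(p04$mask), 1L)
  expect_identical(p04$mask[33, 33], 1L)
})

test_that("lattice-disk pixel count stays inside the pi*(r-1)^2..pi*(r+1)^2 band", {
  for (r in c(2, 3.5, 5, 9, 14.2, 20, 28)) {
    n <- sum(synth_patch(nodule_spec(radius_px = r, center = c(32, 32),
                                     noise_sd = 0))$mask)
    expect_gte(n, pi * (r - 1)^2)
    expect_lte(n, pi * (r + 1)^2)
  }
})

test_that("rendering is deterministic and leaves the caller's RNG untouched", {
  sp <- nodule_spec("juxta_vascular", center = c(30, 30), radius_px = 6,
                    seed = 99)
  a <- synth_patch(sp); b <- synth_patch(sp)
  expect_identical(a$image, b$image)
  expect_identical(a$mask, b$mask)
  set.seed(123); x1 <- runif(1)
  set.seed(123); invisible(synth_patch(sp)); x2 <- runif(1)
  expect_identical(x1, x2)
})

test_that("wall bands and vessel ridges go into the image, never the mask", {
  types <- c("well_circumscribed", "juxta_pleural", "juxta_vascular")
  geom <- list(center = c(10, 30), radius_px = 6, contrast = 0.5,
               noise_sd = 0, seed = 5)
  ps <- lapply(types, function(t) synth_patch(do.call(nodule_spec, c(t, geom))))
  # identical masks (pure disk) across nodule types
  expect_identical(ps[[1]]$mask, ps[[2]]$mask)
  expect_identical(ps[[1]]$mask, ps[[3]]$mask)
  # but the attached structures brighten pixels outside the mask
  outside <- ps[[1]]$mask == 0
  expect_gt(sum(ps[[2]]$image[outside] - ps[[1]]$image[outside]), 1)
  expect_gt(sum(ps[[3]]$image[outside] - ps[[1]]$image[outside]), 1)
  # intensities clipped to [0, 1]
  for (p in ps) expect_true(all(p$image >= 0 & p$image <= 1))
})

test_that("degenerate nodule placements are rejected", {
  expect_error(nodule_spec(center = c(70, 32)), "degenerate")
  expect_error(nodule_spec(center = c(-1, 0)), "degenerate")
  expect_error(nodule_spec(radius_px = 0), "radius_px")
})

test_that("dataset generation reproduces counts, mixes and seeds", {
  s <- synth_dataset(300, type_mix = c(1, 1, 1) / 3, seed = 21)
  expect_length(s, 300)
  counts <- table(factor(vapply(s, function(x) x$spec$nodule_type, ""),
                         levels = c("well_circumscribed", "juxta_pleural",
                                    "juxta_vascular")))
  # 99.99% binomial band for p = 1/3, n = 300
  expect_true(all(counts >= 60 & counts <= 140))
  expect_true(all(vapply(s, function(x) sum(x$mask) >= 1, TRUE)))
  # degenerate mix and reproducibility
  one <- synth_dataset(1, type_mix = c(1, 0, 0), seed = 3)
  expect_identical(one[[1]]$spec$nodule_type, "well_circumscribed")
  expect_identical(synth_dataset(4, seed = 9)[[2]]$image,
                   synth_dataset(4, seed = 9)[[2]]$image)
  expect_error(synth_dataset(0), "positive")
  expect_error(synth_dataset(5, type_mix = c(1, 1, 1)), "sum to 1")
})

test_that("horizontal flip doubles the set and is an involution", {
  s <- synth_dataset(6, seed = 13)
  aug <- flip_augment(s)
  expect_length(aug, 12)
  expect_identical(aug[[7]]$id, paste0(s[[1]]$id, "_flip"))
  # mirroring twice restores image and mask exactly
  twice <- flip_augment(aug[7:12])[7:12]
  for (i in 1:6) {
    expect_identical(twice[[i]]$image, s[[i]]$image)
    expect_identical(twice[[i]]$mask, s[[i]]$mask)
  }
  expect_identical(flip_augment(list()), list())
})

test_that("metrics are invariant under jointly mirroring both masks", {
  set.seed(31)
  g <- random_mask(16, 16, 0.3); p <- random_mask(16, 16, 0.3)
  gm <- g[, 16:1]; pm <- p[, 16:1]
  expect_identical(seg_metrics(g, p)[1:4], seg_metrics(gm, pm)[1:4])
})

test_that("splitting is an exact, reproducible partition", {
  s <- synth_dataset(10, seed = 17)
  sp <- split_dataset(s, 0.8, seed = 5)
  expect_length(sp$train, 8)
  expect_length(sp$test, 2)
  ids <- function(x) sort(vapply(x, `[[`, "", "id"))
  expect_identical(sort(c(ids(sp$train), ids(sp$test))), ids(s))
  expect_length(intersect(ids(sp$train), ids(sp$test)), 0)
  sp2 <- split_dataset(s, 0.8, seed = 5)
  expect_identical(ids(sp$train), ids(sp2$train))
  sp3 <- split_dataset(s, 0.8, seed = 6)
  expect_length(sp3$train, 8)          # sizes unchanged under a new seed
  expect_error(split_dataset(s[1], 0.8), "at least 2")
  expect_error(split_dataset(s, 1.2), "between 0 and 1")
})

test_that("crop_and_resize: identity crops come back bit-for-bit", {
  set.seed(2)
  img <- matrix(runif(128 * 128), 128, 128)
  box <- c(row_min = 10, col_min = 20, row_max = 74, col_max = 84)
  expect_identical(crop_and_resize(img, box), img[11:74, 21:84])
})

test_that("bicubic upscaling reproduces a planar ramp exactly", {
  a <- 0.013; b <- -0.007; cc <- 0.4
  img <- outer(0:127, 0:127, function(r, co) a * r + b * co + cc)
  box <- c(row_min = 40, col_min = 40, row_max = 72, col_max = 72)  # 32x32
  out <- crop_and_resize(img, box, c(64, 64))
  # oracle: evaluate the plane at the corner-aligned sample coordinates
  src <- (0:63) * 31 / 63
  expected <- outer(src, src, function(r, co) a * (40 + r) + b * (40 + co) + cc)
  expect_lt(max(abs(out - expected)), 1e-6)
})

test_that("constant crops resize to the same constant and bad boxes error", {
  img <- matrix(0.37, 50, 50)
  out <- crop_and_resize(img, c(5, 5, 15, 40), c(64, 64))
  expect_true(all(abs(out - 0.37) < 1e-12))
  expect_error(crop_and_resize(img, c(5, 5, 5, 40)), "empty")
  expect_error(crop_and_resize(img, c(-1, 0, 10, 10)), "outside")
  expect_error(crop_and_resize(img, c(0, 0, 51, 10)), "outside")
})

test_that("datasets round-trip through PNG + CSV within 8-bit precision", {
  s <- synth_dataset(3, seed = 23)
  dir <- file.path(tempdir(), "ds_roundtrip")
  unlink(dir, recursive = TRUE)
  write_dataset(s, dir, split = c("train", "train", "test"))
  idx <- read.csv(file.path(dir, "index.csv"))
  expect_identical(names(idx),
                   c("id", "image_path", "mask_path", "nodule_type", "split"))
  back <- read_dataset(dir)
  for (i in 1:3) {
    expect_identical(back[[i]]$mask, s[[i]]$mask + 0L)
    expect_lt(max(abs(back[[i]]$image - s[[i]]$image)), 1 / 255)
  }
  expect_length(read_dataset(dir, split = "test"), 1)
})
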