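# Synthetic nodule phantoms: 64x64 grayscale patches containing one bright
# quasi-circular nodule on a darker textured background, with a pixel-exact
# binary ground-truth mask. Juxta-pleural phantoms add a bright wall band
# touching the nodule, juxta-vascular phantoms a vessel-like ridge through
# it; both are rendered in the image only, never in the mask, so the
# segmentation target is always "nodule vs everything else".

.PATCH_SIZE <- 64L
.NODULE_TYPES <- c("well_circumscribed", "juxta_pleural", "juxta_vascular")

# run expr with a private RNG stream; the caller's RNG state is untouched
.with_seed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

#' Nodule phantom specification
#'
#' Geometry and rendering parameters of one synthetic nodule patch. Pixel
#' coordinates are 0-based `(row, col)` on the 64x64 grid. The radius is in
#' pixels; the physical 3-30 mm diameter range of screen-detected nodules is
#' mapped linearly onto 4-56 px diameters (so radii of 2-28 px) by the
#' dataset generator.
#'
#' @param nodule_type One of `"well_circumscribed"`, `"juxta_pleural"`,
#'   `"juxta_vascular"`.
#' @param center Numeric `(row, col)`, 0-based, inside the 64x64 grid.
#' @param radius_px Positive nodule radius in pixels.
#' @param contrast Nodule-over-background intensity gap in (0, 1].
#' @param noise_sd Additive Gaussian pixel noise standard deviation.
#' @param seed Integer seed making the rendering deterministic.
#' @return A `nodule_spec` object.
#' @export
nodule_spec <- function(nodule_type = "well_circumscribed", center = c(32, 32),
                        radius_px = 8, contrast = 0.5, noise_sd = 0.05,
                        seed = 1L) {
  nodule_type <- match.arg(nodule_type, .NODULE_TYPES)
  stopifnot(length(center) == 2, is.finite(radius_px), radius_px > 0,
            contrast > 0, contrast <= 1, noise_sd >= 0)
  if (any(center < 0) || any(center > .PATCH_SIZE - 1))
    stop("degenerate nodule: center outside the 64x64 grid")
  structure(list(nodule_type = nodule_type, center = as.numeric(center),
                 radius_px = as.numeric(radius_px), contrast = contrast,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "nodule_spec")
}

# separable moving-average smoothing with edge padding (box kernel run twice
# per axis, giving an approximately Gaussian response)
.smooth2d <- function(m, half = 2L) {
  k <- rep(1, 2 * half + 1) / (2 * half + 1)
  pad <- function(v) c(rep(v[1], half), v, rep(v[length(v)], half))
  smooth1 <- function(v) as.numeric(stats::filter(pad(v), k, sides = 2))[(half + 1):(half + length(v))]
  for (pass in 1:2) {
    m <- apply(m, 2, smooth1)
    m <- t(apply(m, 1, smooth1))
  }
  m
}

#' Render one synthetic nodule patch
#'
#' Deterministically renders the 64x64 intensity patch and its pixel-exact
#' binary mask from a [nodule_spec()]. The mask is the closed Euclidean
#' disk: exactly those pixels whose center lies within `radius_px` of
#' `center`. A juxta-pleural wall band or juxta-vascular vessel ridge is
#' drawn into the image only, never into the mask. Intensities are clipped
#' to \[0, 1\].
#'
#' @param spec A [nodule_spec()].
#' @return A `patch_sample`: list with `image` (64x64 matrix in \[0, 1\]),
#'   `mask` (64x64 0/1 integer matrix), `spec`, and `id`.
#' @examples
#' p <- synth_patch(nodule_spec(radius_px = 5, noise_sd = 0))
#' sum(p$mask)  # 81 pixels in the closed radius-5 lattice disk
#' @export
synth_patch <- function(spec) {
  stopifnot(inherits(spec, "nodule_spec"))
  n <- .PATCH_SIZE
  rows <- matrix(0:(n - 1), n, n)
  cols <- matrix(0:(n - 1), n, n, byrow = TRUE)
  d2 <- (rows - spec$center[1])^2 + (cols - spec$center[2])^2
  mask <- (d2 <= spec$radius_px^2 * (1 + 1e-12)) * 1L
  if (sum(mask) == 0) stop("degenerate nodule: no pixel inside the disk")

  .with_seed(spec$seed, {
    z <- .smooth2d(matrix(stats::rnorm(n * n), n, n))
    bg <- 0.25 + 0.06 * z / max(0.02, stats::sd(z))
    img <- bg
    # radial profile: brightest at the center, still above background at rim
    prof <- 1 - 0.3 * pmin(1, d2 / spec$radius_px^2)
    img <- img + spec$contrast * prof * mask

    if (spec$nodule_type == "juxta_pleural") {
      # bright band along the nearest patch edge, deep enough to overlap
      # the nodule rim by ~2 px
      edge_dist <- c(spec$center[1], n - 1 - spec$center[1],
                     spec$center[2], n - 1 - spec$center[2])
      e <- which.min(edge_dist)
      depth <- max(1, edge_dist[e] - spec$radius_px + 2)
      in_band <- switch(e,
                        rows <= depth, rows >= n - 1 - depth,
                        cols <= depth, cols >= n - 1 - depth)
      img <- pmax(img, bg + spec$contrast * 0.95 * in_band)
    } else if (spec$nodule_type == "juxta_vascular") {
      # vessel-like ridge through the nodule center at a random angle
      theta <- stats::runif(1, 0, pi)
      dline <- abs(cos(theta) * (rows - spec$center[1]) +
                   sin(theta) * (cols - spec$center[2]))
      wv <- max(1.5, 0.25 * spec$radius_px)
      ridge <- spec$contrast * 0.8 * exp(-(dline / wv)^2)
      img <- pmax(img, bg + ridge)
    }
    if (spec$noise_sd > 0)
      img <- img + matrix(stats::rnorm(n * n, sd = spec$noise_sd), n, n)
    img <- pmin(pmax(img, 0), 1)
    structure(list(image = img, mask = mask, spec = spec,
                   id = sprintf("seed%d", spec$seed)),
              class = "patch_sample")
  })
}

#' Generate a synthetic nodule dataset
#'
#' Draws `n` phantom patches whose nodule types follow `type_mix`
#' (well-circumscribed, juxta-pleural, juxta-vascular). Nodule diameters are
#' uniform over the 3-30 mm screening range, mapped linearly to 4-56 px;
#' contrasts are uniform in \[0.35, 0.7\]. Per-sample seeds are derived
#' reproducibly from `seed`, so the same call yields bit-identical samples.
#'
#' @param n Number of patches (positive).
#' @param type_mix Probability triple over the three nodule types; must sum
#'   to 1.
#' @param seed Master seed.
#' @param noise_sd Additive pixel noise standard deviation.
#' @return List of `patch_sample` objects with ids `"s00001"`, ...
#' @export
synth_dataset <- function(n, type_mix = c(1, 1, 1) / 3, seed = 1L,
                          noise_sd = 0.05) {
  if (!is.numeric(n) || length(n) != 1 || n < 1 || n != round(n))
    stop("n must be a positive integer")
  stopifnot(length(type_mix) == 3, all(type_mix >= 0))
  if (abs(sum(type_mix) - 1) > 1e-8) stop("type_mix must sum to 1")
  n <- as.integer(n)
  .with_seed(seed, {
    types <- sample(.NODULE_TYPES, n, replace = TRUE, prob = type_mix)
    seeds <- sample.int(.Machine$integer.max - 1L, n, replace = TRUE)
    dia_mm <- stats::runif(n, 3, 30)
    radius <- (4 + (dia_mm - 3) * 52 / 27) / 2
    contrast <- stats::runif(n, 0.35, 0.7)
    samples <- vector("list", n)
    for (i in seq_len(n)) {
      r <- radius[i]
      lo <- min(r + 2, 30); hi <- max(63 - r - 2, 33)
      ctr <- stats::runif(2, lo, hi)
      if (types[i] == "juxta_pleural") {
        # park the center near a random edge so the wall band reaches the rim
        e <- sample(4L, 1)
        near <- min(stats::runif(1, max(2, r - 2), r + 4), 31)
        ctr <- switch(e, c(near, ctr[2]), c(63 - near, ctr[2]),
                      c(ctr[1], near), c(ctr[1], 63 - near))
      }
      sp <- nodule_spec(types[i], center = ctr, radius_px = r,
                        contrast = contrast[i], noise_sd = noise_sd,
                        seed = seeds[i])
      s <- synth_patch(sp)
      s$id <- sprintf("s%05d", i)
      samples[[i]] <- s
    }
    samples
  })
}

#' Horizontal-flip augmentation
#'
#' Returns the input samples followed by one left-right mirrored copy of
#' each (image and mask mirrored jointly), doubling the dataset size; this
#' is the augmentation used to grow the 2625-nodule corpus to 5250.
#' Mirrored ids get the suffix `"_flip"`.
#'
#' @param samples List of `patch_sample` objects.
#' @return List of length `2 * length(samples)`.
#' @export
flip_augment <- function(samples) {
  stopifnot(is.list(samples))
  mirrored <- lapply(samples, function(s) {
    w <- ncol(s$image)
    s$image <- s$image[, w:1, drop = FALSE]
    s$mask <- s$mask[, w:1, drop = FALSE]
    s$id <- paste0(s$id, "_flip")
    s
  })
  c(samples, mirrored)
}

#' Shuffle and split a dataset into train and test
#'
#' Randomly permutes the samples with `seed` and assigns the first
#' `round(train_fraction * N)` to the training set; with 5250 samples and
#' fraction 0.8 this gives the 4200/1050 split.
#'
#' @param samples List of `patch_sample` objects (at least 2).
#' @param train_fraction Fraction in (0, 1).
#' @param seed Shuffle seed.
#' @return A `dataset_split`: list with `train`, `test`, `train_fraction`,
#'   `seed`.
#' @export
split_dataset <- function(samples, train_fraction = 0.8, seed = 1L) {
  stopifnot(is.list(samples))
  if (length(samples) < 2) stop("need at least 2 samples to split")
  if (!(train_fraction > 0 && train_fraction < 1))
    stop("train_fraction must be strictly between 0 and 1")
  n <- length(samples)
  .with_seed(seed, {
    perm <- sample.int(n)
    ntr <- round(train_fraction * n)
    structure(list(train = samples[perm[seq_len(ntr)]],
                   test = samples[perm[setdiff(seq_len(n), seq_len(ntr))]],
                   train_fraction = train_fraction, seed = as.integer(seed)),
              class = "dataset_split")
  })
}

# Keys cubic-convolution kernel, a = -0.5
.keys <- function(x) {
  x <- abs(x)
  ifelse(x <= 1, 1.5 * x^3 - 2.5 * x^2 + 1,
         ifelse(x < 2, -0.5 * x^3 + 2.5 * x^2 - 4 * x + 2, 0))
}

# 1-D bicubic resample of each column of m from n_in to n_out rows,
# corner-aligned grid, linear extrapolation of the two border taps
.bicubic1d <- function(m, n_out) {
  n_in <- nrow(m)
  if (n_out == n_in) return(m)
  if (n_in == 1) return(m[rep(1, n_out), , drop = FALSE])
  src <- (seq_len(n_out) - 1) * (n_in - 1) / (n_out - 1)
  i0 <- floor(src)
  fr <- src - i0
  # pad by linear extrapolation so polynomial reproduction holds at borders
  pad <- rbind(2 * m[1, ] - m[2, ], m, 2 * m[n_in, ] - m[n_in - 1, ])
  out <- matrix(0, n_out, ncol(m))
  for (t in -1:2) {
    w <- .keys(fr - t)
    idx <- pmin(n_in, pmax(-1, i0 + t)) + 2  # clamp into padded range
    out <- out + pad[idx, , drop = FALSE] * w
  }
  out
}

#' Crop a bounding box and resize to a fixed patch size
#'
#' Crops the half-open, 0-based box `[row_min, row_max) x [col_min,
#' col_max)` from `image` and resamples it to `out_size` with bicubic
#' (Keys, a = -0.5) interpolation on a corner-aligned grid; this is the ROI
#' preprocessing applied to detected nodules before segmentation. When the
#' box already has the output size the crop is returned unchanged. Output
#' values are clipped to the range of the cropped region.
#'
#' @param image Numeric matrix.
#' @param box Numeric/integer vector or list with `row_min`, `col_min`,
#'   `row_max`, `col_max` (0-based, half-open).
#' @param out_size Output `(height, width)`, default `c(64, 64)`.
#' @return `out_size` numeric matrix.
#' @export
crop_and_resize <- function(image, box, out_size = c(64L, 64L)) {
  stopifnot(is.matrix(image), length(out_size) == 2, all(out_size >= 1))
  b <- as.list(box)
  need <- c("row_min", "col_min", "row_max", "col_max")
  if (is.null(names(b)) || !all(need %in% names(b))) {
    stopifnot(length(b) == 4)
    names(b) <- need
  }
  b <- lapply(b, as.numeric)
  if (b$row_max <= b$row_min || b$col_max <= b$col_min)
    stop("empty bounding box")
  if (b$row_min < 0 || b$col_min < 0 ||
      b$row_max > nrow(image) || b$col_max > ncol(image))
    stop("bounding box outside the image")
  crop <- image[(b$row_min + 1):b$row_max, (b$col_min + 1):b$col_max,
                drop = FALSE]
  if (all(dim(crop) == out_size)) return(crop)
  out <- .bicubic1d(crop, out_size[1])
  out <- t(.bicubic1d(t(out), out_size[2]))
  pmin(pmax(out, min(crop)), max(crop))
}

#' @export
print.patch_sample <- function(x, ...) {
  cat("<patch_sample> id=", x$id, "  ", nrow(x$image), "x", ncol(x$image),
      "  foreground px: ", sum(x$mask), sep = "")
  if (!is.null(x$spec))
    cat("  type: ", x$spec$nodule_type, "  r=", round(x$spec$radius_px, 1),
        sep = "")
  cat("\n")
  invisible(x)
}

#' @export
print.dataset_split <- function(x, ...) {
  cat("<dataset_split> train: ", length(x$train), "  test: ", length(x$test),
      "  fraction: ", x$train_fraction, "  seed: ", x$seed, "\n", sep = "")
  invisible(x)
}
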