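# Dataset persistence: patches and masks as 8-bit grayscale PNG (mask
# values 0/255 on disk, 0/1 in memory) plus a CSV index.

#' Write a patch dataset to a directory
#'
#' Writes each sample's image and mask as 8-bit grayscale PNGs under
#' `images/` and `masks/`, and an `index.csv` with columns `id`,
#' `image_path`, `mask_path`, `nodule_type`, `split`.
#'
#' @param samples List of `patch_sample` objects.
#' @param dir Output directory (created if missing).
#' @param split Optional character vector (one of `"train"`, `"test"`, or
#'   `""`) per sample, recorded in the index.
#' @return The index path, invisibly.
#' @export
write_dataset <- function(samples, dir, split = NULL) {
  stopifnot(is.list(samples), length(samples) >= 1)
  dir.create(file.path(dir, "images"), recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "masks"), recursive = TRUE, showWarnings = FALSE)
  if (is.null(split)) split <- rep("", length(samples))
  stopifnot(length(split) == length(samples))
  rows <- vector("list", length(samples))
  for (i in seq_along(samples)) {
    s <- samples[[i]]
    ip <- file.path("images", paste0(s$id, ".png"))
    mp <- file.path("masks", paste0(s$id, ".png"))
    png::writePNG(s$image, file.path(dir, ip))
    png::writePNG(s$mask + 0, file.path(dir, mp))
    rows[[i]] <- data.frame(
      id = s$id, image_path = ip, mask_path = mp,
      nodule_type = if (!is.null(s$spec)) s$spec$nodule_type else "",
      split = split[i], stringsAsFactors = FALSE)
  }
  idx <- file.path(dir, "index.csv")
  utils::write.csv(do.call(rbind, rows), idx, row.names = FALSE)
  invisible(idx)
}

#' Read a patch dataset from a directory
#'
#' Reads the `index.csv` written by [write_dataset()] and loads images and
#' masks back into `patch_sample` objects (mask pixels are re-binarized
#' from their 0/255 disk encoding).
#'
#' @param dir Dataset directory.
#' @param split If non-`NULL`, keep only rows whose `split` column matches.
#' @return List of `patch_sample` objects.
#' @export
read_dataset <- function(dir, split = NULL) {
  idx <- utils::read.csv(file.path(dir, "index.csv"),
                         stringsAsFactors = FALSE)
  if (!is.null(split)) idx <- idx[idx$split %in% split, , drop = FALSE]
  lapply(seq_len(nrow(idx)), function(i) {
    img <- png::readPNG(file.path(dir, idx$image_path[i]))
    if (length(dim(img)) == 3) img <- img[, , 1]
    msk <- png::readPNG(file.path(dir, idx$mask_path[i]))
    if (length(dim(msk)) == 3) msk <- msk[, , 1]
    structure(list(image = img, mask = (msk > 0.5) * 1L, spec = NULL,
                   id = idx$id[i]),
              class = "patch_sample")
  })
}

# stack sample images/masks into [64, 64, 1, N] arrays for the engine
.samples_to_arrays <- function(samples) {
  n <- length(samples)
  d <- dim(samples[[1]]$image)
  x <- array(0, c(d[1], d[2], 1, n))
  y <- array(0, c(d[1], d[2], 1, n))
  for (i in seq_len(n)) {
    x[, , 1, i] <- samples[[i]]$image
    y[, , 1, i] <- samples[[i]]$mask
  }
  list(x = x, y = y)
}
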