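#' Training configuration
#'
#' Optimization settings for [train()]. Defaults reproduce the published
#' recipe: minibatch 32, 200 epochs, pixel-wise binary cross-entropy, Adam
#' with beta1 = 0.99 (as printed, although 0.9 is the usual convention; it
#' can be overridden here), beta2 = 0.999, learning rate 0.001, and
#' decoupled weight decay 5e-4 applied to convolution/dense weights only.
#'
#' @param batch_size Minibatch size (>= 1).
#' @param epochs Number of epochs (>= 0).
#' @param learning_rate Adam step size (> 0).
#' @param beta1,beta2 Adam moment decay rates.
#' @param eps Adam denominator offset.
#' @param weight_decay Decoupled weight-decay coefficient.
#' @param val_fraction Fraction of the training split carved off (by
#'   `seed`) as a validation set for the loss curve; 0 disables validation.
#' @param seed Seed controlling the validation carve-out, minibatch
#'   shuffling order and nothing else.
#' @return A `train_config` object.
#' @export
train_config <- function(batch_size = 32L, epochs = 200L,
                         learning_rate = 1e-3, beta1 = 0.99, beta2 = 0.999,
                         eps = 1e-7, weight_decay = 5e-4,
                         val_fraction = 0.1, seed = 1L) {
  stopifnot(batch_size >= 1, epochs >= 0, learning_rate > 0,
            beta1 >= 0, beta1 < 1, beta2 >= 0, beta2 < 1,
            val_fraction >= 0, val_fraction < 1)
  structure(list(batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs), learning_rate = learning_rate,
                 beta1 = beta1, beta2 = beta2, eps = eps,
                 weight_decay = weight_decay, val_fraction = val_fraction,
                 seed = as.integer(seed)),
            class = "train_config")
}

#' Train a segmentation network
#'
#' Minibatch Adam training of a [build_segnet()] or [build_unet()] network
#' on the training half of a [split_dataset()] (or a plain list of
#' `patch_sample` objects), minimizing pixel-wise binary cross-entropy.
#' A `val_fraction` of the training samples is held out for the validation
#' loss curve, and the weights with the best validation loss are retained
#' as a checkpoint. Fully reproducible given `config$seed` and the
#' network's initialization seed.
#'
#' @param net A `noduleseg_net`; its weights are updated in place.
#' @param split A `dataset_split` (only its `train` half is used) or a list
#'   of `patch_sample` objects.
#' @param config A [train_config()].
#' @return A `segnet_fit`: list with `net`, `log` (data.frame of epoch,
#'   train_loss, val_loss, wall_time), `config`, `best` (epoch, val_loss,
#'   weights), and final `weights`.
#' @export
train <- function(net, split, config = train_config()) {
  stopifnot(inherits(net, "noduleseg_net"), inherits(config, "train_config"))
  samples <- if (inherits(split, "dataset_split")) split$train else split
  if (!is.list(samples) || length(samples) == 0)
    stop("empty training set")
  nval <- floor(config$val_fraction * length(samples))
  val <- NULL
  if (nval >= 1) {
    idx <- .with_seed(config$seed, sample.int(length(samples), nval))
    val <- samples[idx]
    samples <- samples[-idx]
    if (length(samples) == 0) stop("empty training set after validation carve-out")
  }
  tr <- .samples_to_arrays(samples)
  va <- if (!is.null(val)) .samples_to_arrays(val)
  ptr <- .net_ptr(net)

  log <- data.frame(epoch = integer(), train_loss = numeric(),
                    val_loss = numeric(), wall_time = numeric())
  best <- list(epoch = NA_integer_, val_loss = Inf, weights = NULL)
  for (ep in seq_len(config$epochs)) {
    ep_seed <- (config$seed + 7919 * ep) %% .Machine$integer.max
    t0 <- proc.time()[["elapsed"]]
    ls <- eng_train(ptr, tr$x, tr$y, 1L, config$batch_size,
                    config$learning_rate, config$beta1, config$beta2,
                    config$eps, config$weight_decay, as.integer(ep_seed),
                    if (!is.null(va)) va$x else NULL,
                    if (!is.null(va)) va$y else NULL)
    wt <- proc.time()[["elapsed"]] - t0
    log <- rbind(log, data.frame(epoch = ep, train_loss = ls[1, 1],
                                 val_loss = ls[1, 2], wall_time = wt))
    if (!is.null(va) && is.finite(ls[1, 2]) && ls[1, 2] < best$val_loss)
      best <- list(epoch = ep, val_loss = ls[1, 2], weights = net_weights(net))
  }
  structure(list(net = net, log = log, config = config, best = best,
                 weights = net_weights(net)),
            class = "segnet_fit")
}

#' Evaluate a network on labelled patches
#'
#' Runs deterministic inference on each sample, thresholds the probability
#' maps with [binarize()], and aggregates the four overlap metrics with
#' [batch_report()].
#'
#' @param net A `noduleseg_net` or a `segnet_fit`.
#' @param samples Non-empty list of `patch_sample` objects.
#' @param threshold Foreground decision threshold.
#' @param batch_size Inference batch size.
#' @return A `seg_report`.
#' @export
evaluate <- function(net, samples, threshold = 0.5, batch_size = 32L) {
  if (inherits(net, "segnet_fit")) net <- net$net
  stopifnot(inherits(net, "noduleseg_net"))
  if (!is.list(samples) || length(samples) == 0)
    stop("empty evaluation set")
  n <- length(samples)
  preds <- vector("list", n)
  for (s0 in seq(1, n, by = batch_size)) {
    ix <- s0:min(n, s0 + batch_size - 1)
    a <- .samples_to_arrays(samples[ix])
    p <- forward(net, a$x, train = FALSE, drop = FALSE)
    for (j in seq_along(ix))
      preds[[ix[j]]] <- binarize(p[, , 1, j], threshold)
  }
  batch_report(lapply(samples, `[[`, "mask"), preds,
               ids = vapply(samples, `[[`, character(1), "id"))
}

#' @export
print.segnet_fit <- function(x, ...) {
  cat("<segnet_fit> ", x$net$kind, ", ", nrow(x$log), " epochs\n", sep = "")
  if (nrow(x$log) > 0) {
    cat(sprintf("  final train BCE: %.5f", x$log$train_loss[nrow(x$log)]))
    if (is.finite(x$log$val_loss[nrow(x$log)]))
      cat(sprintf("   val BCE: %.5f", x$log$val_loss[nrow(x$log)]))
    cat("\n")
    if (!is.na(x$best$epoch))
      cat(sprintf("  best val BCE %.5f at epoch %d\n",
                  x$best$val_loss, x$best$epoch))
  }
  invisible(x)
}

#' @export
summary.segnet_fit <- function(object, ...) {
  cat("Training summary\n")
  print(object)
  cat("  parameters:",
      format(count_trainable_parameters(object$net), big.mark = ","), "\n")
  if (nrow(object$log) > 0)
    cat(sprintf("  mean epoch wall time: %.2fs\n", mean(object$log$wall_time)))
  invisible(object)
}

#' Predict segmentation masks or probability maps
#'
#' @param object A `segnet_fit`.
#' @param newdata Patches accepted by [forward()] (list of samples, matrix,
#'   or array).
#' @param type `"prob"` for probability maps, `"mask"` for binarized masks.
#' @param threshold Threshold used when `type = "mask"`.
#' @param ... Unused.
#' @return Array of probabilities or 0/1 masks.
#' @export
predict.segnet_fit <- function(object, newdata, type = c("prob", "mask"),
                               threshold = 0.5, ...) {
  type <- match.arg(type)
  p <- forward(object$net, newdata, train = FALSE)
  if (type == "mask") binarize(p, threshold) else p
}

#' Plot training and validation loss curves
#'
#' @param x A `segnet_fit`.
#' @param ... Passed to [graphics::matplot()].
#' @export
plot.segnet_fit <- function(x, ...) {
  if (nrow(x$log) == 0) stop("no epochs logged")
  has_val <- any(is.finite(x$log$val_loss))
  ys <- if (has_val) cbind(x$log$train_loss, x$log$val_loss) else
    cbind(x$log$train_loss)
  graphics::matplot(x$log$epoch, ys, type = "l", lty = 1,
                    col = c("black", "firebrick")[seq_len(ncol(ys))],
                    xlab = "epoch", ylab = "binary cross-entropy", ...)
  graphics::legend("topright", bty = "n",
                   legend = c("train", "validation")[seq_len(ncol(ys))],
                   col = c("black", "firebrick")[seq_len(ncol(ys))], lty = 1)
  invisible(x)
}
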