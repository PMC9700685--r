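#' Segmentation network specification
#'
#' Assembles the hyperparameters of the pyramidal-attention encoder-decoder:
#' two encoder stages of two inverted residual blocks (32 then 64 filters)
#' each followed by 2x2 max-pooling, a feature-pyramid attention bridge, two
#' decoder stages (64 then 32 filters) each preceded by bilinear 2x
#' upsampling with a 1x1 projection, skip concatenations from the pre-pool
#' encoder features, and a 1-channel 1x1 sigmoid head.
#'
#' The defaults are the calibrated configuration whose trainable-parameter
#' count is exactly 891,713 for a 64x64x1 input; see the methods vignette
#' for how the under-specified hyperparameters (expansion factor, bias and
#' normalization placement, pyramid width) were fixed.
#'
#' @param input_shape Height, width, channels of the input patch.
#' @param encoder_filters Filter counts of the two encoder stages.
#' @param decoder_filters Filter counts of the two decoder stages; must be
#'   the reverse of `encoder_filters`.
#' @param ir_kernel Depth-wise kernel size inside the inverted residual
#'   blocks.
#' @param se_ratio Squeeze-excitation ratio.
#' @param expansion Expansion factor of the inverted residual blocks.
#' @param bridge A [pyramid_config()]; its `channels` must equal the last
#'   encoder filter count.
#' @return A `segnet_spec` object.
#' @export
segnet_spec <- function(input_shape = c(64L, 64L, 1L),
                        encoder_filters = c(32L, 64L),
                        decoder_filters = c(64L, 32L),
                        ir_kernel = 3L, se_ratio = 0.25, expansion = 4L,
                        bridge = pyramid_config(channels = encoder_filters[2])) {
  stopifnot(length(input_shape) == 3, length(encoder_filters) == 2,
            length(decoder_filters) == 2)
  if (!all(decoder_filters == rev(encoder_filters)))
    stop("decoder_filters must be the reverse of encoder_filters")
  if (bridge$channels != encoder_filters[2])
    stop("bridge channel count must equal the last encoder filter count")
  lv <- bridge$levels
  if ((input_shape[1] %/% 4) %% (2^lv) != 0)
    stop("input spatial dims must leave the bridge divisible by 2^levels")
  structure(list(input_shape = as.integer(input_shape),
                 encoder_filters = as.integer(encoder_filters),
                 decoder_filters = as.integer(decoder_filters),
                 ir_kernel = as.integer(ir_kernel), se_ratio = se_ratio,
                 expansion = as.integer(expansion), bridge = bridge),
            class = "segnet_spec")
}

.ir_cfg <- function(spec, cin, filters) {
  ir_block_config(cin, filters, kernel = spec$ir_kernel,
                  se_ratio = spec$se_ratio, expansion = spec$expansion)
}

#' Build the pyramidal-attention segmentation network
#'
#' Constructs the full encoder-decoder with the feature-pyramid attention
#' bridge and He-normal initial weights, backed by the package's compiled
#' engine. With the default [segnet_spec()] the network has exactly
#' 891,713 trainable parameters.
#'
#' @param spec A [segnet_spec()].
#' @param seed He-normal initialization seed; the build is deterministic
#'   given the seed.
#' @param precision `"single"` (default; used for training speed) or
#'   `"double"`.
#' @return A `noduleseg_net` object.
#' @examples
#' net <- build_segnet()
#' count_trainable_parameters(net)
#' trace_shapes(net)
#' @export
build_segnet <- function(spec = segnet_spec(), seed = 1L, precision = "single") {
  stopifnot(inherits(spec, "segnet_spec"))
  ef <- spec$encoder_filters
  df <- spec$decoder_filters
  g <- .g_new()
  i <- .g_input(g, spec$input_shape[1], spec$input_shape[2], spec$input_shape[3])

  e1 <- .g_ir_block(g, i, .ir_cfg(spec, spec$input_shape[3], ef[1]))
  e1 <- .g_ir_block(g, e1, .ir_cfg(spec, ef[1], ef[1]))
  .g_tag(g, e1, "Encoder block 1", 1L)
  p1 <- .g_maxpool(g, e1)
  .g_tag(g, p1, "Maxpooling layer 1", 1L)

  e2 <- .g_ir_block(g, p1, .ir_cfg(spec, ef[1], ef[2]))
  e2 <- .g_ir_block(g, e2, .ir_cfg(spec, ef[2], ef[2]))
  .g_tag(g, e2, "Encoder block 2", 2L)
  p2 <- .g_maxpool(g, e2)
  .g_tag(g, p2, "Maxpooling layer 2", 2L)

  br <- .g_fpa(g, p2, spec$bridge)
  .g_tag(g, br, "Pyramidal attention block", 3L)

  u1 <- .g_upsample(g, br)
  u1 <- .g_conv(g, u1, 1L, df[1], bias = FALSE)
  u1 <- .g_bn_swish(g, u1)
  .g_tag(g, u1, "Upsampling layer 1", 4L)
  c1 <- .g_concat(g, u1, e2)
  .g_tag(g, c1, "Concatenation", 4L)
  d1 <- .g_ir_block(g, c1, .ir_cfg(spec, df[1] + ef[2], df[1]))
  d1 <- .g_ir_block(g, d1, .ir_cfg(spec, df[1], df[1]))
  .g_tag(g, d1, "Decoder block 1", 4L)

  u2 <- .g_upsample(g, d1)
  u2 <- .g_conv(g, u2, 1L, df[2], bias = FALSE)
  u2 <- .g_bn_swish(g, u2)
  .g_tag(g, u2, "Upsampling layer 2", 5L)
  c2 <- .g_concat(g, u2, e1)
  .g_tag(g, c2, "Concatenation", 5L)
  d2 <- .g_ir_block(g, c2, .ir_cfg(spec, df[2] + ef[1], df[2]))
  d2 <- .g_ir_block(g, d2, .ir_cfg(spec, df[2], df[2]))
  .g_tag(g, d2, "Decoder block 2", 5L)

  hd <- .g_conv(g, d2, 1L, 1L, bias = TRUE)
  out <- .g_act(g, hd, "sigmoid")
  .g_tag(g, out, "Convolutional layer (1 x 1)", 6L)

  .net_new(g, seed, precision, "segnet", spec)
}

#' Build a classic U-Net baseline
#'
#' Contracting/expanding U-Net with double 3x3 convolution blocks (swish
#' activations), 2x2 max-pool downsampling, bilinear upsampling with a 2x2
#' up-convolution halving the channels, skip concatenation, and a 1x1
#' sigmoid head. Serves as the reference architecture the pyramid-attention
#' network is compared against; its parameter count grows with `depth` and
#' `base_filters` and is far above the pyramid-attention network at the
#' classic depth-4, 64-filter configuration.
#'
#' @param depth Number of pooling steps; `input_size` must be divisible by
#'   `2^depth`.
#' @param base_filters Filter count of the first stage; doubled at each
#'   deeper stage.
#' @param input_size Spatial side length of the square input.
#' @param in_channels Input channel count.
#' @param seed He-normal initialization seed.
#' @param precision `"single"` (default) or `"double"`.
#' @return A `noduleseg_net` object.
#' @export
build_unet <- function(depth = 4L, base_filters = 64L, input_size = 64L,
                       in_channels = 1L, seed = 1L, precision = "single") {
  stopifnot(depth >= 1, base_filters >= 1)
  if (input_size %% (2^depth) != 0)
    stop("input size ", input_size, " is not divisible by 2^", depth)
  g <- .g_new()
  x <- .g_input(g, input_size, input_size, in_channels)
  dbl <- function(x, f) {
    x <- .g_conv(g, x, 3L, f, bias = TRUE); x <- .g_act(g, x, "swish")
    x <- .g_conv(g, x, 3L, f, bias = TRUE); .g_act(g, x, "swish")
  }
  skips <- integer(depth)
  for (l in seq_len(depth)) {
    f <- base_filters * 2^(l - 1)
    x <- dbl(x, f)
    skips[l] <- x
    x <- .g_maxpool(g, x)
  }
  x <- dbl(x, base_filters * 2^depth)
  for (l in rev(seq_len(depth))) {
    f <- base_filters * 2^(l - 1)
    x <- .g_upsample(g, x)
    x <- .g_conv(g, x, 2L, f, bias = TRUE)   # 2x2 up-convolution
    x <- .g_act(g, x, "swish")
    x <- .g_concat(g, x, skips[l])
    x <- dbl(x, f)
  }
  x <- .g_conv(g, x, 1L, 1L, bias = TRUE)
  .g_act(g, x, "sigmoid")
  .net_new(g, seed, precision, "unet")
}

#' Count trainable parameters of a network
#'
#' Sums the elements of every trainable tensor (convolution and dense
#' weights, biases, batch-norm scale and shift); batch-norm running
#' statistics are excluded. The count is a property of the architecture:
#' it does not depend on the initialization seed or on any input data.
#'
#' @param net A `noduleseg_net`.
#' @return Number of trainable parameters.
#' @examples
#' count_trainable_parameters(build_segnet())  # 891713
#' @export
count_trainable_parameters <- function(net) {
  stopifnot(inherits(net, "noduleseg_net"))
  eng_nparams(.net_ptr(net))
}

#' Trace feature-map shapes through a network
#'
#' Returns the ordered table of named operator outputs (level, operator,
#' height x width x channels) for the tagged stages of the network, computed
#' from the layer graph. For [build_segnet()] this reproduces the 12-row
#' feature-map table of the architecture: encoder blocks, poolings, the
#' pyramidal attention bridge, upsamplings, concatenations, decoder blocks
#' and the final 1x1 convolution.
#'
#' @param net A `noduleseg_net`.
#' @return A `data.frame` with columns `level`, `operator`, `height`,
#'   `width`, `channels`.
#' @export
trace_shapes <- function(net) {
  stopifnot(inherits(net, "noduleseg_net"))
  rows <- Filter(function(n) !is.na(n$tag), net$graph)
  data.frame(level = vapply(rows, function(n) n$level, integer(1)),
             operator = vapply(rows, function(n) n$tag, character(1)),
             height = vapply(rows, function(n) n$H, integer(1)),
             width = vapply(rows, function(n) n$W, integer(1)),
             channels = vapply(rows, function(n) n$C, integer(1)),
             stringsAsFactors = FALSE)
}

# normalize user input to an [H, W, C, N] array matching the network input
.as_input_array <- function(net, x) {
  s <- net$graph[[1]]
  if (is.list(x)) {
    imgs <- lapply(x, function(p) if (inherits(p, "patch_sample")) p$image else p)
    x <- array(unlist(imgs, use.names = FALSE), dim = c(dim(imgs[[1]]), 1, length(imgs)))
  }
  d <- dim(x)
  if (is.null(d) || length(d) < 2) stop("input must be a matrix or array")
  if (length(d) == 2) dim(x) <- c(d, 1L, 1L)
  else if (length(d) == 3) {
    # H x W x C (single sample) if third dim matches channels, else batch
    if (d[3] == s$C) dim(x) <- c(d, 1L) else dim(x) <- c(d[1], d[2], 1L, d[3])
  }
  d <- dim(x)
  if (d[1] != s$H || d[2] != s$W || d[3] != s$C)
    stop("input shape ", paste(d[1:3], collapse = "x"),
         " does not match the network input ",
         paste(c(s$H, s$W, s$C), collapse = "x"))
  if (!all(is.finite(x))) stop("input contains non-finite values")
  x
}

#' Run a forward pass
#'
#' Applies the network to one patch or a batch of patches. Inference mode
#' (`train = FALSE`, the default) is deterministic: batch normalization uses
#' its running statistics, so identical inputs give identical outputs.
#'
#' @param net A `noduleseg_net`.
#' @param x A `H x W` matrix, `H x W x C` array, `H x W x C x N` array, or
#'   list of patches / `patch_sample` objects.
#' @param train Use batch statistics (training mode) instead of running
#'   statistics.
#' @param drop Drop unit dimensions of the result (default `TRUE`: a single
#'   64x64x1 prediction comes back as a 64x64 matrix).
#' @return Numeric array of network outputs; for the segmentation networks,
#'   per-pixel foreground probabilities strictly inside (0, 1).
#' @export
forward <- function(net, x, train = FALSE, drop = TRUE) {
  stopifnot(inherits(net, "noduleseg_net"))
  xa <- .as_input_array(net, x)
  out <- eng_forward(.net_ptr(net), xa, isTRUE(train))
  if (drop) {
    d <- dim(out)
    out <- array(out, dim = d)
    if (all(d[3:4] == 1)) dim(out) <- d[1:2]
    else if (d[3] == 1) dim(out) <- d[c(1, 2, 4)]
    else if (d[4] == 1) dim(out) <- d[1:3]
  }
  out
}

#' Threshold a probability map into a binary mask
#'
#' @param prob_map Numeric array with values in \[0, 1\].
#' @param threshold Decision threshold in \[0, 1\]; a pixel is foreground
#'   iff its probability is `>= threshold`.
#' @return Integer array of 0/1 with the same shape.
#' @export
binarize <- function(prob_map, threshold = 0.5) {
  if (!is.numeric(threshold) || length(threshold) != 1 ||
      is.na(threshold) || threshold < 0 || threshold > 1)
    stop("threshold must be a single value in [0, 1]")
  stopifnot(is.numeric(prob_map), all(prob_map >= 0 & prob_map <= 1))
  out <- prob_map >= threshold
  storage.mode(out) <- "integer"
  out
}

#' Extract or restore network weights
#'
#' `net_weights()` returns every parameter tensor (and batch-norm running
#' statistics) as a plain list; `set_net_weights()` writes such a list back.
#' Together they implement checkpointing: save the list with `saveRDS()`,
#' rebuild the network with its builder, and restore.
#'
#' @param net A `noduleseg_net`.
#' @param weights A list previously returned by `net_weights()` for a
#'   network with the same architecture.
#' @return `net_weights()`: a list with one entry per graph node;
#'   `set_net_weights()`: the network, invisibly.
#' @export
net_weights <- function(net) {
  stopifnot(inherits(net, "noduleseg_net"))
  eng_weights(.net_ptr(net))
}

#' @rdname net_weights
#' @export
set_net_weights <- function(net, weights) {
  stopifnot(inherits(net, "noduleseg_net"))
  eng_set_weights(.net_ptr(net), weights)
  invisible(net)
}

#' @export
print.noduleseg_net <- function(x, ...) {
  cat("<noduleseg_net> ", x$kind, "\n", sep = "")
  s <- x$graph[[1]]
  cat("  input: ", s$H, "x", s$W, "x", s$C,
      "   nodes: ", length(x$graph),
      "   precision: ", x$precision, "\n", sep = "")
  cat("  trainable parameters: ",
      format(count_trainable_parameters(x), big.mark = ","), "\n", sep = "")
  invisible(x)
}
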