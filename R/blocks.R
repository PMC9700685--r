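#' Swish activation
#'
#' Computes `x * sigmoid(x)` elementwise. Swish is smooth, non-monotone for
#' negative inputs (global minimum of about -0.2785 near x = -1.278), and
#' unlike ReLU has no region of exactly-zero gradient, so no unit can die
#' during training. It is the activation used throughout the segmentation
#' network's inverted residual blocks.
#'
#' @param x Numeric vector, matrix or array.
#' @return Object of the same shape as `x`.
#' @examples
#' swish(0)        # 0
#' swish(c(-1, 1))
#' @export
swish <- function(x) {
  stopifnot(is.numeric(x), all(is.finite(x)))
  x * stats::plogis(x)
}

#' Convolution cost specification
#'
#' Describes one convolutional layer for the multiply-accumulate cost model:
#' an `hi` x `wi` input feature map with `di` channels, `dj` output channels
#' and a square `f` x `f` filter.
#'
#' @param hi,wi Input height and width in pixels.
#' @param di,dj Input and output channel counts.
#' @param f Square filter side length.
#' @return A `conv_cost_spec` object.
#' @seealso [conv_cost_standard()], [conv_cost_depthwise()],
#'   [cost_reduction_factor()]
#' @export
conv_cost_spec <- function(hi, wi, di, dj, f) {
  v <- c(hi = hi, wi = wi, di = di, dj = dj, f = f)
  if (any(!is.finite(v)) || any(v < 1) || any(v != round(v)))
    stop("all cost-spec fields must be positive integers")
  structure(as.list(v), class = "conv_cost_spec")
}

.as_cost_spec <- function(spec) {
  if (inherits(spec, "conv_cost_spec")) return(spec)
  do.call(conv_cost_spec, as.list(spec))
}

#' Computational cost of a standard convolution
#'
#' Multiply-accumulate count of an ordinary convolution:
#' `hi * wi * di * dj * f^2`. Every output channel mixes every input channel
#' at every spatial position, which is what makes standard convolutions the
#' dominant cost in encoder-decoder segmentation networks.
#'
#' @param spec A [conv_cost_spec()].
#' @return Non-negative number of multiply-accumulates.
#' @examples
#' conv_cost_standard(conv_cost_spec(16, 16, 64, 64, 3))  # 9437184
#' @export
conv_cost_standard <- function(spec) {
  s <- .as_cost_spec(spec)
  s$hi * s$wi * s$di * s$dj * s$f * s$f
}

#' Computational cost of a depth-wise separable convolution
#'
#' Multiply-accumulate count of a depth-wise convolution followed by a 1x1
#' point-wise mixing convolution: `hi * wi * di * (f^2 + dj)`. The spatial
#' filter is applied once per input channel instead of once per input-output
#' channel pair, which is the parameter- and compute-saving trick inside the
#' inverted residual block.
#'
#' @inheritParams conv_cost_standard
#' @return Non-negative number of multiply-accumulates.
#' @examples
#' conv_cost_depthwise(conv_cost_spec(16, 16, 64, 64, 3))  # 1196032
#' @export
conv_cost_depthwise <- function(spec) {
  s <- .as_cost_spec(spec)
  s$hi * s$wi * s$di * (s$f^2 + s$dj)
}

#' Cost reduction factor of depth-wise over standard convolution
#'
#' Returns `f^2 * dj / (f^2 + dj)`, the ratio of the standard convolution
#' cost to the depth-wise separable cost for the same layer. For f = 3 the
#' factor approaches 9 as the output channel count grows, i.e. the
#' depth-wise form is roughly nine times cheaper.
#'
#' @inheritParams conv_cost_standard
#' @return Positive real reduction factor.
#' @examples
#' cost_reduction_factor(conv_cost_spec(16, 16, 64, 64, 3))  # 576/73
#' @export
cost_reduction_factor <- function(spec) {
  s <- .as_cost_spec(spec)
  s$f^2 * s$dj / (s$f^2 + s$dj)
}

#' Inverted residual block configuration
#'
#' Hyperparameters of one inverted residual block: a narrow-wide-narrow
#' bottleneck that expands the input by `expansion` with a 1x1 convolution,
#' filters spatially with a depth-wise `kernel` x `kernel` convolution,
#' reweights channels by squeeze-excitation with bottleneck
#' `ceiling(se_ratio * in_channels)`, and projects linearly back to
#' `filters` channels, with an identity skip when `stride == 1` and
#' `in_channels == filters`.
#'
#' @param in_channels Input channel count.
#' @param filters Output channel count.
#' @param kernel Odd depth-wise kernel size (default 3).
#' @param stride Stride; only 1 is supported (the network downsamples by
#'   max-pooling instead).
#' @param se_ratio Squeeze-excitation ratio in (0, 1], default 0.25.
#' @param expansion Positive integer width multiplier of the expanded middle
#'   stage; the package default of 4 is the calibrated value under which the
#'   assembled network's trainable-parameter count equals the published
#'   891,713 (see the methods vignette).
#' @param conv_bias,se_bias Bias flags for the convolutions and the two
#'   squeeze-excitation dense layers. Defaults follow the calibrated
#'   configuration: convolutions carry batch normalization instead of
#'   biases, and the SE dense layers are bias-free.
#' @return An `ir_block_config` object.
#' @export
ir_block_config <- function(in_channels, filters, kernel = 3L, stride = 1L,
                            se_ratio = 0.25, expansion = 4L,
                            conv_bias = FALSE, se_bias = FALSE) {
  stopifnot(in_channels >= 1, filters >= 1, kernel >= 1, kernel %% 2 == 1,
            se_ratio > 0, se_ratio <= 1, expansion >= 1)
  if (stride != 1L)
    stop("only stride 1 is supported; downsampling is done by max-pooling")
  if (ceiling(se_ratio * expansion * in_channels) < 1)
    stop("squeeze-excitation bottleneck would be empty")
  structure(list(in_channels = as.integer(in_channels),
                 filters = as.integer(filters), kernel = as.integer(kernel),
                 stride = as.integer(stride), se_ratio = se_ratio,
                 expansion = as.integer(expansion),
                 conv_bias = isTRUE(conv_bias), se_bias = isTRUE(se_bias)),
            class = "ir_block_config")
}

#' Pyramid attention configuration
#'
#' Configuration of the feature-pyramid attention bridge: kernel sizes of
#' the successive down-path convolutions (strictly decreasing, all odd),
#' the channel count of the feature map entering the bridge, and the
#' internal width of the pyramid convolutions. The default width of 92 is
#' the calibrated value (see the methods vignette).
#'
#' @param kernel_sizes Strictly decreasing odd kernel sizes, default
#'   `c(7, 5, 3)`.
#' @param channels Bridge channel count (64 in the default network).
#' @param width Internal pyramid channel width.
#' @param bias Should pyramid convolutions carry biases? Default `FALSE`.
#' @param main_conv Should the gate multiply a 1x1-convolved main branch
#'   (`TRUE`) or the incoming feature map directly (`FALSE`, default: the
#'   attention branch itself ends in the 1x1 projection)?
#' @return A `pyramid_config` object.
#' @export
pyramid_config <- function(kernel_sizes = c(7L, 5L, 3L), channels = 64L,
                           width = 92L, bias = FALSE, main_conv = FALSE) {
  stopifnot(length(kernel_sizes) >= 1, all(kernel_sizes %% 2 == 1),
            all(diff(kernel_sizes) < 0), channels >= 1, width >= 1)
  structure(list(kernel_sizes = as.integer(kernel_sizes),
                 levels = length(kernel_sizes),
                 channels = as.integer(channels), width = as.integer(width),
                 bias = isTRUE(bias), main_conv = isTRUE(main_conv)),
            class = "pyramid_config")
}

# ---------------------------------------------------------------------------
# Standalone single-block networks. These wrap one block into a live engine
# graph so the block can be probed (forward passes, weight surgery,
# parameter counts) in isolation.

#' Single-block network: squeeze-excitation
#'
#' Builds a network containing exactly one squeeze-excitation gate: global
#' average pool, dense bottleneck of `ceiling(ratio * channels)` units with
#' swish, dense layer back to `channels` units with a logistic gate, and a
#' per-channel multiplicative rescaling of the input.
#'
#' @param channels Channel count of the input feature map.
#' @param ratio Bottleneck ratio in (0, 1].
#' @param height,width Spatial dims of the input.
#' @param bias Should the two dense layers carry biases? Default `TRUE` for
#'   the standalone block (the calibrated in-network configuration uses
#'   `FALSE`).
#' @param seed He-normal initialization seed.
#' @return A `noduleseg_net` that can be passed to [forward()],
#'   [net_weights()] and [set_net_weights()].
#' @export
se_network <- function(channels, ratio = 0.25, height = 8L, width = 8L,
                       bias = TRUE, seed = 1L) {
  stopifnot(ceiling(ratio * channels) >= 1)
  g <- .g_new()
  i <- .g_input(g, height, width, channels)
  z <- .g_gap(g, i)
  z <- .g_conv(g, z, 1L, max(1L, as.integer(ceiling(ratio * channels))), bias = bias)
  z <- .g_act(g, z, "swish")
  z <- .g_conv(g, z, 1L, channels, bias = bias)
  z <- .g_act(g, z, "sigmoid")
  .g_chanscale(g, i, z)
  .net_new(g, seed, "double", "squeeze_excite")
}

#' Single-block network: inverted residual block
#'
#' @param cfg An [ir_block_config()].
#' @param height,width Spatial dims of the input feature map.
#' @param seed He-normal initialization seed.
#' @param precision `"double"` (default) or `"single"`.
#' @return A `noduleseg_net`.
#' @export
ir_network <- function(cfg, height = 8L, width = 8L, seed = 1L,
                       precision = "double") {
  stopifnot(inherits(cfg, "ir_block_config"))
  g <- .g_new()
  i <- .g_input(g, height, width, cfg$in_channels)
  .g_ir_block(g, i, cfg)
  .net_new(g, seed, precision, "inverted_residual")
}

#' Single-block network: feature pyramid attention
#'
#' @param cfg A [pyramid_config()].
#' @param height,width Spatial dims of the input feature map; must be
#'   divisible by `2^length(cfg$kernel_sizes)`.
#' @param seed He-normal initialization seed.
#' @param precision `"double"` (default) or `"single"`.
#' @return A `noduleseg_net`.
#' @export
fpa_network <- function(cfg = pyramid_config(), height = 16L, width = 16L,
                        seed = 1L, precision = "double") {
  stopifnot(inherits(cfg, "pyramid_config"))
  g <- .g_new()
  i <- .g_input(g, height, width, cfg$channels)
  .g_fpa(g, i, cfg)
  .net_new(g, seed, precision, "feature_pyramid_attention")
}

#' Apply a squeeze-excitation gate to a feature map
#'
#' Functional form of the squeeze-excitation block: each channel of `fm` is
#' multiplied by a scalar gate in (0, 1) derived from the globally pooled
#' channel statistics through a bottleneck of `ceiling(ratio * C)` units.
#' Spatial dims and channel count are unchanged.
#'
#' @param fm Numeric array `H x W x C`.
#' @param ratio Bottleneck ratio in (0, 1].
#' @param weights Optional weight list from [net_weights()] of a matching
#'   [se_network()]; if omitted, weights are He-normal from `seed`.
#' @param seed Initialization seed used when `weights` is missing.
#' @param bias Bias flag forwarded to [se_network()].
#' @return Array of the same shape as `fm`.
#' @export
squeeze_excite <- function(fm, ratio = 0.25, weights = NULL, seed = 1L,
                           bias = TRUE) {
  stopifnot(is.array(fm), length(dim(fm)) == 3)
  d <- dim(fm)
  net <- se_network(d[3], ratio, d[1], d[2], bias = bias, seed = seed)
  if (!is.null(weights)) set_net_weights(net, weights)
  forward(net, fm)
}

#' Apply one inverted residual block to a feature map
#'
#' Functional form of the inverted residual block (see
#' [ir_block_config()] for the stage structure). The skip connection is
#' active exactly when `cfg$stride == 1` and `cfg$in_channels ==
#' cfg$filters`. Batch normalization runs in inference mode (identity
#' standardization under fresh statistics).
#'
#' @param fm Numeric array `H x W x C` with `C == cfg$in_channels`.
#' @param cfg An [ir_block_config()].
#' @param weights Optional weight list from [net_weights()].
#' @param seed Initialization seed used when `weights` is missing.
#' @return Array `H x W x cfg$filters`.
#' @export
inverted_residual <- function(fm, cfg, weights = NULL, seed = 1L) {
  stopifnot(is.array(fm), length(dim(fm)) == 3)
  d <- dim(fm)
  if (d[3] != cfg$in_channels)
    stop("feature map has ", d[3], " channels but config expects ",
         cfg$in_channels)
  net <- ir_network(cfg, d[1], d[2], seed = seed)
  if (!is.null(weights)) set_net_weights(net, weights)
  forward(net, fm)
}

#' Apply the feature pyramid attention bridge to a feature map
#'
#' Functional form of the bridge between encoder and decoder: the input is
#' pooled and convolved down a three-level pyramid (7x7, 5x5, 3x3 by
#' default), the levels are fused bottom-up by bilinear upsampling and
#' addition, a 1x1 convolution projects the fused map to a pixel-wise gate,
#' and the gate multiplies the incoming feature map (or its 1x1-convolved
#' main branch when `cfg$main_conv`). Output shape equals input shape.
#'
#' @param fm Numeric array `H x W x C` with `C == cfg$channels`; `H` and
#'   `W` must be divisible by `2^cfg$levels`.
#' @param cfg A [pyramid_config()].
#' @param weights Optional weight list from [net_weights()].
#' @param seed Initialization seed used when `weights` is missing.
#' @return Array of the same shape as `fm`.
#' @export
feature_pyramid_attention <- function(fm, cfg = pyramid_config(), weights = NULL,
                                      seed = 1L) {
  stopifnot(is.array(fm), length(dim(fm)) == 3)
  d <- dim(fm)
  if (d[3] != cfg$channels)
    stop("feature map has ", d[3], " channels but config expects ",
         cfg$channels)
  net <- fpa_network(cfg, d[1], d[2], seed = seed)
  if (!is.null(weights)) set_net_weights(net, weights)
  forward(net, fm)
}
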