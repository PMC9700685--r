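# Internal layer-graph builder. A graph is a list of node descriptors in
# topological order; the C++ engine allocates parameters and buffers from it.
# Every node records its output shape (H, W, C) so shape tracing is pure
# arithmetic on the R side.

.g_new <- function() {
  g <- new.env(parent = emptyenv())
  g$nodes <- list()
  g
}

.g_shape <- function(g, id) {
  n <- g$nodes[[id]]
  c(n$H, n$W, n$C)
}

.g_push <- function(g, op, inputs, H, W, C, k = 0L, cin = 0L, cout = 0L,
                    bias = FALSE, tag = NA_character_, level = NA_integer_) {
  g$nodes[[length(g$nodes) + 1L]] <- list(
    op = op, `in` = as.integer(inputs), k = as.integer(k),
    cin = as.integer(cin), cout = as.integer(cout), bias = isTRUE(bias),
    H = as.integer(H), W = as.integer(W), C = as.integer(C),
    tag = tag, level = as.integer(level))
  length(g$nodes)
}

.g_input <- function(g, H, W, C) .g_push(g, "input", integer(), H, W, C)

.g_conv <- function(g, i, k, cout, bias = FALSE) {
  s <- .g_shape(g, i)
  .g_push(g, "conv", i, s[1], s[2], cout, k = k, cin = s[3], cout = cout, bias = bias)
}

.g_dwconv <- function(g, i, k, bias = FALSE) {
  s <- .g_shape(g, i)
  .g_push(g, "dwconv", i, s[1], s[2], s[3], k = k, cin = s[3], cout = s[3], bias = bias)
}

.g_bn <- function(g, i) {
  s <- .g_shape(g, i)
  .g_push(g, "bn", i, s[1], s[2], s[3])
}

.g_act <- function(g, i, kind = "swish") {
  s <- .g_shape(g, i)
  .g_push(g, kind, i, s[1], s[2], s[3])
}

# fused batch-norm + swish (one engine node; same parameters as plain BN)
.g_bn_swish <- function(g, i) {
  s <- .g_shape(g, i)
  .g_push(g, "bnswish", i, s[1], s[2], s[3])
}

.g_gap <- function(g, i) {
  s <- .g_shape(g, i)
  .g_push(g, "gap", i, 1L, 1L, s[3])
}

.g_chanscale <- function(g, i, gate) {
  s <- .g_shape(g, i)
  .g_push(g, "chanscale", c(i, gate), s[1], s[2], s[3])
}

.g_mul <- function(g, a, b) {
  s <- .g_shape(g, a)
  .g_push(g, "mul", c(a, b), s[1], s[2], s[3])
}

.g_add <- function(g, a, b) {
  s <- .g_shape(g, a)
  .g_push(g, "add", c(a, b), s[1], s[2], s[3])
}

.g_concat <- function(g, a, b) {
  sa <- .g_shape(g, a); sb <- .g_shape(g, b)
  stopifnot(sa[1] == sb[1], sa[2] == sb[2])
  .g_push(g, "concat", c(a, b), sa[1], sa[2], sa[3] + sb[3])
}

.g_maxpool <- function(g, i) {
  s <- .g_shape(g, i)
  stopifnot(s[1] %% 2 == 0, s[2] %% 2 == 0)
  .g_push(g, "maxpool", i, s[1] %/% 2, s[2] %/% 2, s[3])
}

.g_upsample <- function(g, i) {
  s <- .g_shape(g, i)
  .g_push(g, "upsample", i, s[1] * 2L, s[2] * 2L, s[3])
}

.g_tag <- function(g, id, tag, level) {
  g$nodes[[id]]$tag <- tag
  g$nodes[[id]]$level <- as.integer(level)
  invisible(id)
}

# Inverted residual block, MobileNetV3/EfficientNet convention:
# 1x1 expansion conv + BN + swish; depth-wise conv + BN + swish;
# squeeze-excitation on the expanded tensor with bottleneck
# ceiling(se_ratio * input channels); linear 1x1 projection + BN;
# identity skip when stride is 1 and channel counts match.
.g_ir_block <- function(g, i, cfg) {
  s <- .g_shape(g, i)
  cin <- s[3]
  if (cin != cfg$in_channels)
    stop("inverted residual block: input has ", cin, " channels, config expects ",
         cfg$in_channels)
  e <- cfg$expansion * cin
  x <- .g_conv(g, i, 1L, e, bias = cfg$conv_bias)
  x <- .g_bn_swish(g, x)
  x <- .g_dwconv(g, x, cfg$kernel, bias = cfg$conv_bias)
  x <- .g_bn_swish(g, x)
  sq <- max(1L, as.integer(ceiling(cfg$se_ratio * cin)))
  z <- .g_gap(g, x)
  z <- .g_conv(g, z, 1L, sq, bias = cfg$se_bias)
  z <- .g_act(g, z, "swish")
  z <- .g_conv(g, z, 1L, e, bias = cfg$se_bias)
  z <- .g_act(g, z, "sigmoid")
  x <- .g_chanscale(g, x, z)
  x <- .g_conv(g, x, 1L, cfg$filters, bias = cfg$conv_bias)
  x <- .g_bn(g, x)
  if (cfg$stride == 1L && cin == cfg$filters) x <- .g_add(g, x, i)
  x
}

# Feature pyramid attention bridge: three successive maxpool + conv stages
# (7x7, 5x5, 3x3 by default) at an internal width, fused bottom-up by
# bilinear upsampling and addition, projected back to the input channel
# count by a 1x1 convolution, and applied as a multiplicative pixel-wise
# gate on the bridge feature map (optionally on a 1x1-convolved main branch).
.g_fpa <- function(g, i, cfg) {
  s <- .g_shape(g, i)
  if (s[3] != cfg$channels)
    stop("pyramid attention: input has ", s[3], " channels, config expects ",
         cfg$channels)
  lv <- length(cfg$kernel_sizes)
  if (s[1] %% (2^lv) != 0 || s[2] %% (2^lv) != 0)
    stop("pyramid attention: spatial dims (", s[1], "x", s[2],
         ") must be divisible by ", 2^lv)
  down <- integer(lv)
  x <- i
  for (l in seq_len(lv)) {
    x <- .g_maxpool(g, x)
    x <- .g_conv(g, x, cfg$kernel_sizes[l], cfg$width, bias = cfg$bias)
    x <- .g_act(g, x, "swish")
    down[l] <- x
  }
  up <- down[lv]
  for (l in rev(seq_len(lv - 1L))) {
    up <- .g_upsample(g, up)
    up <- .g_add(g, up, down[l])
  }
  up <- .g_upsample(g, up)
  gate <- .g_conv(g, up, 1L, cfg$channels, bias = cfg$bias)
  main <- if (cfg$main_conv) .g_conv(g, i, 1L, cfg$channels, bias = cfg$bias) else i
  .g_mul(g, main, gate)
}

# closed-form trainable-parameter count of a graph (cross-check for the
# engine's own count)
.g_count_params <- function(nodes) {
  tot <- 0
  for (n in nodes) {
    tot <- tot + switch(n$op,
      conv    = n$k * n$k * n$cin * n$cout + if (n$bias) n$cout else 0,
      dwconv  = n$k * n$k * n$cout + if (n$bias) n$cout else 0,
      bn      = 2 * n$C,
      bnswish = 2 * n$C,
      0)
  }
  tot
}

# wrap a finished graph into a live network object backed by the C++ engine
.net_new <- function(g, seed, precision, kind, spec = NULL) {
  ptr <- eng_create(g$nodes, precision)
  eng_init(ptr, as.integer(seed))
  structure(list(graph = g$nodes, ptr = ptr, seed = as.integer(seed),
                 precision = precision, kind = kind, spec = spec),
            class = "noduleseg_net")
}

# engine pointers do not survive serialization; rebuild lazily from the
# graph plus a stored weight list when needed
.net_ptr <- function(net) {
  ok <- tryCatch({ eng_nparams(net$ptr); TRUE }, error = function(e) FALSE)
  if (!ok) stop("network engine pointer is no longer valid; rebuild the ",
                "network with its builder and restore weights with set_net_weights()")
  net$ptr
}
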