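# Architectural building blocks: convolution units, the stem and
# squeeze-and-excitation residual blocks of the encoder, atrous spatial
# pyramid pooling, the two attention gates (original max-pool form and the
# modified stride-2 atrous form) and the decoder upsampling units.
#
# Each builder returns an "af_layer" environment holding its parameters and
# a forward closure over autodiff nodes; `block_apply()` runs a block on a
# plain (N,H,W,C) array.

glorot_uniform <- function(dims, fan_in, fan_out) {
  limit <- sqrt(6 / (fan_in + fan_out))
  array(stats::runif(prod(dims), -limit, limit), dim = dims)
}

new_layer <- function(type, params = list(), children = list(), forward) {
  ly <- new.env(parent = emptyenv())
  ly$type <- type
  ly$params <- params
  ly$children <- children
  ly$forward <- forward
  class(ly) <- "af_layer"
  ly
}

make_conv <- function(kh, kw, cin, cout, stride = 1L, dilation = 1L,
                      use_bias = TRUE) {
  w <- ag_param(glorot_uniform(c(kh, kw, cin, cout),
                               kh * kw * cin, kh * kw * cout), "conv_w")
  b <- if (use_bias) ag_param(numeric(cout), "conv_b") else NULL
  params <- if (use_bias) list(w = w, b = b) else list(w = w)
  new_layer("conv", params, forward = function(x, training = FALSE)
    ag_conv2d(x, w, b, stride = stride, dilation = dilation))
}

make_conv_transpose <- function(cin, cout) {
  w <- ag_param(glorot_uniform(c(2, 2, cin, cout), 4 * cin, 4 * cout), "tconv_w")
  b <- ag_param(numeric(cout), "tconv_b")
  new_layer("conv_transpose", list(w = w, b = b),
            forward = function(x, training = FALSE) ag_conv2d_transpose(x, w, b))
}

make_bn <- function(c, momentum = 0.9, eps = 1e-3) {
  ly <- new_layer("bn",
                  list(gamma = ag_param(rep(1, c), "bn_gamma"),
                       beta = ag_param(numeric(c), "bn_beta"),
                       running_mean = ag_param(numeric(c), "bn_mean", trainable = FALSE),
                       running_var = ag_param(rep(1, c), "bn_var", trainable = FALSE)),
                  forward = NULL)
  ly$momentum <- momentum
  ly$eps <- eps
  ly$forward <- function(x, training = FALSE)
    ag_batchnorm(x, ly$params$gamma, ly$params$beta, ly, training)
  ly
}

make_dense <- function(cin, cout, use_bias = FALSE) {
  w <- ag_param(glorot_uniform(c(cin, cout), cin, cout), "dense_w")
  new_layer("dense", list(w = w),
            forward = function(x, training = FALSE) ag_dense(x, w))
}

# Squeeze-and-excitation: global pool -> bottleneck dense (ReLU) ->
# expanding dense (sigmoid) -> per-channel rescaling.
make_se <- function(c, ratio = 8L) {
  r <- max(c %/% ratio, 1L)
  d1 <- make_dense(c, r)
  d2 <- make_dense(r, c)
  new_layer("se", children = list(d1 = d1, d2 = d2),
            forward = function(x, training = FALSE) {
              g <- ag_global_avg_pool(x)
              g <- ag_relu(d1$forward(g))
              g <- ag_sigmoid(d2$forward(g))
              ag_scale_channels(x, g)
            })
}

make_stem <- function(cin, filters) {
  c1 <- make_conv(3, 3, cin, filters)
  bn1 <- make_bn(filters)
  c2 <- make_conv(3, 3, filters, filters)
  sc <- make_conv(1, 1, cin, filters)
  bns <- make_bn(filters)
  se <- make_se(filters)
  new_layer("stem", children = list(c1 = c1, bn1 = bn1, c2 = c2, sc = sc,
                                    bns = bns, se = se),
            forward = function(x, training = FALSE) {
              h <- c2$forward(ag_relu(bn1$forward(c1$forward(x), training)))
              s <- bns$forward(sc$forward(x), training)
              se$forward(ag_add(h, s), training)
            })
}

# Pre-activation residual block with squeeze-and-excitation; stride 2 in the
# first convolution and in the projected shortcut when downsampling.
make_resblock <- function(cin, filters, stride = 1L) {
  bn1 <- make_bn(cin)
  c1 <- make_conv(3, 3, cin, filters, stride = stride)
  bn2 <- make_bn(filters)
  c2 <- make_conv(3, 3, filters, filters)
  sc <- make_conv(1, 1, cin, filters, stride = stride)
  bns <- make_bn(filters)
  se <- make_se(filters)
  new_layer("resblock", children = list(bn1 = bn1, c1 = c1, bn2 = bn2,
                                        c2 = c2, sc = sc, bns = bns, se = se),
            forward = function(x, training = FALSE) {
              d <- dim(ag_value(x))
              if (stride == 2L && (d[2] %% 2L || d[3] %% 2L))
                stop("residual_block: downsampling requires even spatial dims, got ",
                     d[2], "x", d[3])
              h <- c1$forward(ag_relu(bn1$forward(x, training)))
              h <- c2$forward(ag_relu(bn2$forward(h, training)))
              s <- bns$forward(sc$forward(x), training)
              se$forward(ag_add(h, s), training)
            })
}

# Atrous spatial pyramid pooling.  Two styles:
#  * "sum":    four parallel 3x3 convolutions at rates 1, 6, 12 and 18
#              (each conv -> BN -> ReLU), summed and fused by a 1x1
#              convolution.  This is the style whose parameter budget the
#              built-in variants are calibrated against.
#  * "concat": five parallel paths -- 1x1 conv, 3x3 convolutions at rates
#              6/12/18 and a global-average-pool path (pool -> 1x1 conv ->
#              broadcast back), each conv -> BN -> ReLU, concatenated and
#              fused by a 1x1 conv -> BN -> ReLU.
make_aspp <- function(cin, filters, style = c("sum", "concat")) {
  style <- match.arg(style)
  if (style == "sum") {
    convs <- lapply(c(1, 6, 12, 18), function(r)
      make_conv(3, 3, cin, filters, dilation = r))
    bns <- lapply(1:4, function(i) make_bn(filters))
    fuse <- make_conv(1, 1, filters, filters)
    ch <- c(convs, bns, list(fuse = fuse))
    names(ch)[1:8] <- c(paste0("conv", 1:4), paste0("bn", 1:4))
    new_layer("aspp_sum", children = ch,
              forward = function(x, training = FALSE) {
                paths <- lapply(1:4, function(i)
                  ag_relu(bns[[i]]$forward(convs[[i]]$forward(x), training)))
                y <- ag_add(ag_add(paths[[1]], paths[[2]]),
                            ag_add(paths[[3]], paths[[4]]))
                fuse$forward(y)
              })
  } else {
    p1 <- make_conv(1, 1, cin, filters); b1 <- make_bn(filters)
    p2 <- make_conv(3, 3, cin, filters, dilation = 6); b2 <- make_bn(filters)
    p3 <- make_conv(3, 3, cin, filters, dilation = 12); b3 <- make_bn(filters)
    p4 <- make_conv(3, 3, cin, filters, dilation = 18); b4 <- make_bn(filters)
    pp <- make_conv(1, 1, cin, filters); bp <- make_bn(filters)
    fuse <- make_conv(1, 1, 5 * filters, filters); bf <- make_bn(filters)
    new_layer("aspp_concat",
              children = list(p1 = p1, b1 = b1, p2 = p2, b2 = b2, p3 = p3,
                              b3 = b3, p4 = p4, b4 = b4, pp = pp, bp = bp,
                              fuse = fuse, bf = bf),
              forward = function(x, training = FALSE) {
                d <- dim(ag_value(x))
                y1 <- ag_relu(b1$forward(p1$forward(x), training))
                y2 <- ag_relu(b2$forward(p2$forward(x), training))
                y3 <- ag_relu(b3$forward(p3$forward(x), training))
                y4 <- ag_relu(b4$forward(p4$forward(x), training))
                g <- ag_global_avg_pool(x)
                g <- ag_broadcast_spatial(g, 1L, 1L)
                g <- ag_relu(bp$forward(pp$forward(g), training))
                g <- ag_broadcast_spatial(
                  ag_global_avg_pool(g), d[2], d[3])
                y <- ag_concat_channels(ag_concat_channels(y1, y2),
                                        ag_concat_channels(y3, y4))
                y <- ag_concat_channels(y, g)
                ag_relu(bf$forward(fuse$forward(y), training))
              })
  }
}

# Attention gate between an encoder skip map E at (2H, 2W, Cg) and a decoder
# map D at (H, W, Cx).  The encoder path is BN -> ReLU -> 3x3 conv followed
# by either a 2x2 max pool ("maxpool_original") or a stride-2 atrous 3x3
# convolution with BN ("atrous_modified"); it is summed with the processed
# decoder path, refined by a further BN -> ReLU -> 3x3 conv, squashed by a
# sigmoid and multiplied elementwise onto D.
make_attention <- function(cg, cx, style = c("atrous_modified", "maxpool_original")) {
  style <- match.arg(style)
  bne <- make_bn(cg)
  ce <- make_conv(3, 3, cg, cx)
  atr <- if (style == "atrous_modified") make_conv(3, 3, cx, cx, stride = 2L,
                                                  dilation = 2L) else NULL
  bna <- if (style == "atrous_modified") make_bn(cx) else NULL
  bnd <- make_bn(cx)
  cd <- make_conv(3, 3, cx, cx)
  bng <- make_bn(cx)
  cgt <- make_conv(3, 3, cx, cx)
  ch <- list(bne = bne, ce = ce, bnd = bnd, cd = cd, bng = bng, cgt = cgt)
  if (style == "atrous_modified") ch <- c(ch, list(atr = atr, bna = bna))
  new_layer(paste0("attention_", style), children = ch,
            forward = function(e, d, training = FALSE) {
              de <- dim(ag_value(e)); dd <- dim(ag_value(d))
              if (de[2] != 2L * dd[2] || de[3] != 2L * dd[3])
                stop("attention_block: encoder map must have exactly twice the ",
                     "spatial dims of the decoder map (got ", de[2], "x", de[3],
                     " vs ", dd[2], "x", dd[3], ")")
              ep <- ce$forward(ag_relu(bne$forward(e, training)))
              ep <- if (style == "atrous_modified")
                bna$forward(atr$forward(ep), training)
              else ag_maxpool2(ep)
              dp <- cd$forward(ag_relu(bnd$forward(d, training)))
              g <- cgt$forward(ag_relu(bng$forward(ag_add(ep, dp), training)))
              ag_mul(ag_sigmoid(g), d)
            })
}

make_upsample <- function(mode = c("transpose_conv", "nearest_upsample"),
                          cin = NULL, cout = NULL) {
  mode <- match.arg(mode)
  if (mode == "transpose_conv") {
    tc <- make_conv_transpose(cin, cout)
    new_layer("upsample_tconv", children = list(tc = tc),
              forward = function(x, training = FALSE) tc$forward(x))
  } else {
    new_layer("upsample_nearest",
              forward = function(x, training = FALSE) ag_upsample_nearest2(x))
  }
}

# Flatten all ag_param objects below a layer (depth first, stable order).
collect_params <- function(layer) {
  out <- list()
  if (!is.null(layer$params)) out <- unname(layer$params)
  for (ch in layer$children) out <- c(out, collect_params(ch))
  out
}

# ---- exported surface ------------------------------------------------------

#' Feature map shape descriptor
#'
#' Describes the `(batch, height, width, channels)` contract threaded through
#' all block operations.  Internally feature maps are stored as plain R
#' arrays with `dim = c(batch, height, width, channels)`.
#'
#' @param batch,height,width,channels Positive integers.
#' @return A named integer vector of class `"af_shape"`.
#' @export
feature_map_shape <- function(batch, height, width, channels) {
  v <- c(batch = as.integer(batch), height = as.integer(height),
         width = as.integer(width), channels = as.integer(channels))
  if (any(is.na(v)) || any(v < 1L)) stop("all shape fields must be positive")
  structure(v, class = "af_shape")
}

#' Convolution specification
#'
#' @param kernel Integer pair `(kh, kw)`.
#' @param stride,dilation Positive integers; `dilation` is the atrous rate.
#' @param out_channels Number of output channels.
#' @param use_bias Include an additive bias term.
#' @return A list of class `"af_conv_spec"`.
#' @export
conv_spec <- function(kernel = c(3L, 3L), stride = 1L, dilation = 1L,
                      out_channels, use_bias = TRUE) {
  if (stride < 1L || dilation < 1L)
    stop("stride and dilation must be >= 1")
  if (out_channels < 1L) stop("out_channels must be >= 1")
  structure(list(kernel = as.integer(rep(kernel, length.out = 2)),
                 stride = as.integer(stride), dilation = as.integer(dilation),
                 out_channels = as.integer(out_channels),
                 use_bias = isTRUE(use_bias)),
            class = "af_conv_spec")
}

#' Activation-then-convolution unit
#'
#' The elementary unit of the pre-activation residual style: the activation
#' `g` is applied first and the convolution (with "same" padding) second, so
#' an identity kernel with a linear activation reproduces its input.
#'
#' @param x Feature map array `(N, H, W, C)`.
#' @param spec An [conv_spec()] object.
#' @param weights Optional kernel array `(kh, kw, C, out_channels)`; drawn
#'   from a Glorot-uniform initializer (current RNG stream) when `NULL`.
#' @param bias Optional bias vector of length `out_channels`.
#' @param activation `"relu"` or `"linear"`.
#' @param pre_activation Apply the activation before the convolution
#'   (the default, matching the residual blocks) or after.
#' @return Feature map array `(N, H', W', out_channels)`.
#' @export
conv_unit <- function(x, spec, weights = NULL, bias = NULL,
                      activation = c("relu", "linear"), pre_activation = TRUE) {
  activation <- match.arg(activation)
  stopifnot(inherits(spec, "af_conv_spec"), length(dim(x)) == 4L)
  cin <- dim(x)[4]
  if (is.null(weights))
    weights <- glorot_uniform(c(spec$kernel, cin, spec$out_channels),
                              prod(spec$kernel) * cin,
                              prod(spec$kernel) * spec$out_channels)
  if (dim(weights)[3] != cin)
    stop("conv_unit: kernel expects ", dim(weights)[3],
         " input channels, got ", cin)
  if (is.null(bias) && spec$use_bias) bias <- numeric(spec$out_channels)
  act <- function(v) if (activation == "relu") pmax(v, 0) else v
  xin <- x
  if (pre_activation) {
    xin <- act(x); dim(xin) <- dim(x)
  }
  out <- nn_conv2d(xin, weights, if (is.null(bias)) numeric(0) else bias,
                   spec$stride, spec$dilation)
  if (!pre_activation) {
    d <- dim(out); out <- act(out); dim(out) <- d
  }
  out
}

#' Encoder/decoder pairing of the attention gates
#'
#' For `B` encoder blocks beyond the stem, the decoder stage `d` (starting
#' at 0 at the bridge) consumes the skip of encoder stage `e = B - d`,
#' i.e. `d = -e + B`.
#'
#' @param e Encoder block index (stem = 1).
#' @param B Total number of encoder blocks excluding the stem (3 here).
#' @return List with fields `e`, `d` and `B`.
#' @export
attention_index <- function(e, B = 3L) {
  e <- as.integer(e); B <- as.integer(B)
  if (e < 1L || e > B) stop("encoder index must be in 1..B")
  list(e = e, d = B - e, B = B)
}

#' Build a standalone architectural block
#'
#' These constructors expose the network's building blocks for direct use
#' and testing; [build_model()] assembles them into full variants.  Blocks
#' hold their own randomly initialised parameters (seed via [set.seed()]
#' before construction) and are applied with [block_apply()].
#'
#' @param in_channels Number of channels of the input feature map.
#' @param filters Number of output channels.
#' @param se_ratio Squeeze-and-excitation bottleneck reduction ratio.
#' @return An `"af_layer"` object.
#' @export
stem_block <- function(in_channels, filters, se_ratio = 8L) {
  make_stem(in_channels, filters)
}

#' @rdname stem_block
#' @param downsample Halve the spatial dimensions (stride-2 first
#'   convolution and stride-2 projected shortcut).
#' @export
residual_block <- function(in_channels, filters, downsample = TRUE) {
  make_resblock(in_channels, filters, stride = if (downsample) 2L else 1L)
}

#' @rdname stem_block
#' @param out_channels Channels of the fused pyramid output.
#' @param style `"concat"` for the five-path pyramid (1x1 path, atrous rates
#'   6/12/18, global-pooling path, concatenated) or `"sum"` for the four-path
#'   summed pyramid (rates 1/6/12/18) used by the calibrated model variants.
#' @export
aspp_block <- function(in_channels, out_channels, style = c("concat", "sum")) {
  make_aspp(in_channels, out_channels, match.arg(style))
}

#' @rdname stem_block
#' @param encoder_channels,decoder_channels Channel counts of the encoder
#'   skip map (at twice the spatial size) and the decoder map.
#' @param attention `"atrous_modified"` (stride-2 atrous convolution on the
#'   encoder path) or `"maxpool_original"` (2x2 max pooling).
#' @export
attention_block <- function(encoder_channels, decoder_channels,
                            attention = c("atrous_modified", "maxpool_original")) {
  make_attention(encoder_channels, decoder_channels, match.arg(attention))
}

#' @rdname stem_block
#' @param mode `"transpose_conv"` (learnable 2x2 stride-2 transposed
#'   convolution mapping `in_channels` to `out_channels`) or
#'   `"nearest_upsample"` (parameter-free doubling; channels unchanged).
#' @export
decoder_upsample <- function(mode = c("transpose_conv", "nearest_upsample"),
                             in_channels = NULL, out_channels = NULL) {
  mode <- match.arg(mode)
  if (mode == "transpose_conv" && (is.null(in_channels) || is.null(out_channels)))
    stop("transpose_conv mode needs in_channels and out_channels")
  make_upsample(mode, in_channels, out_channels)
}

#' Apply a block to a feature map
#'
#' @param block An `"af_layer"` from one of the block constructors.
#' @param x Feature map array `(N, H, W, C)`; for attention blocks the
#'   encoder map, with `d` the decoder map.
#' @param d Decoder feature map (attention blocks only).
#' @param training Use batch statistics in the normalization layers and
#'   update their running estimates.
#' @return The resulting feature map as a plain array.
#' @export
block_apply <- function(block, x, d = NULL, training = FALSE) {
  stopifnot(inherits(block, "af_layer"))
  res <- if (is.null(d)) block$forward(x, training = training)
         else block$forward(x, d, training = training)
  ag_value(res)
}

#' Count the parameters of a block or model
#'
#' Sums the sizes of every parameter tensor: convolution kernels and biases,
#' batch-normalization scale/shift and moving statistics, and the
#' squeeze-and-excitation dense layers — i.e. the totals as printed by
#' common framework model summaries.
#'
#' @param object An `"af_layer"` block or an `"af_model"`.
#' @param trainable_only Exclude the batch-normalization moving statistics.
#' @return Integer parameter count.
#' @export
count_parameters <- function(object, trainable_only = FALSE) {
  ps <- if (inherits(object, "af_model")) object$param_list
        else collect_params(object)
  if (trainable_only) ps <- Filter(function(p) isTRUE(p$trainable), ps)
  sum(vapply(ps, function(p) length(p$value), numeric(1)))
}
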