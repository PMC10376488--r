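# Assembly of the three architecture variants and inference.
#
# Encoder: stem + three stride-2 squeeze-and-excitation residual blocks
# (spatial reduction 8x).  Bridge: atrous spatial pyramid pooling.  Decoder:
# three stages of attention gate -> upsampling -> skip concatenation ->
# residual block, followed by a final pyramid block, a 1x1 convolution and a
# sigmoid.  The variants differ only in the attention style and the
# upsampling operator:
#   resunetpp  max-pool attention, nearest upsampling
#   afnet_noT  stride-2 atrous attention, nearest upsampling
#   afnet      stride-2 atrous attention, 2x2 transposed convolutions

#' Declare a model variant
#'
#' @param name One of `"afnet"`, `"afnet_noT"`, `"resunetpp"`.  The name
#'   fixes the attention and upsampling styles.
#' @param filters Encoder filter widths (stem plus the three residual
#'   blocks).  The default, with `bridge = 256`, reproduces the reference
#'   parameter budgets of the three variants (4.07/4.85/4.80 M).
#' @param bridge Channel width of the pyramid bridge.
#' @param input_size `(H, W)`, both divisible by 8.
#' @param aspp_style Pyramid style, see [aspp_block()].
#' @param se_ratio Squeeze-and-excitation reduction ratio.
#' @return A list of class `"af_variant"`.
#' @export
model_variant <- function(name = c("afnet", "afnet_noT", "resunetpp"),
                          filters = c(16L, 32L, 64L, 128L), bridge = 256L,
                          input_size = c(512L, 512L),
                          aspp_style = c("sum", "concat"), se_ratio = 8L) {
  name <- match.arg(name)
  aspp_style <- match.arg(aspp_style)
  input_size <- as.integer(rep(input_size, length.out = 2))
  if (any(input_size %% 8L != 0L))
    stop("input_size must be divisible by 8, got ",
         paste(input_size, collapse = "x"))
  if (length(filters) != 4L) stop("filters must list 4 encoder widths")
  structure(list(
    name = name,
    attention = if (name == "resunetpp") "maxpool_original" else "atrous_modified",
    upsample = if (name == "afnet") "transpose_conv" else "nearest_upsample",
    filters = as.integer(filters), bridge = as.integer(bridge),
    input_size = input_size, aspp_style = aspp_style,
    se_ratio = as.integer(se_ratio)
  ), class = "af_variant")
}

#' Build a segmentation network
#'
#' Instantiates the architecture described by a [model_variant()] with
#' seeded Glorot-uniform weights.
#'
#' @param variant An `"af_variant"` (or a variant name, built with defaults).
#' @param seed Integer seed for weight initialization.
#' @param in_channels Number of input image channels.
#' @return An object of class `"af_model"`.
#' @export
build_model <- function(variant = model_variant(), seed = 1L, in_channels = 1L) {
  if (is.character(variant)) variant <- model_variant(variant)
  stopifnot(inherits(variant, "af_variant"))
  f <- variant$filters; br <- variant$bridge
  old <- get0(".Random.seed", globalenv(), inherits = FALSE)
  set.seed(seed)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))

  L <- list()
  L$stem <- make_stem(in_channels, f[1])
  L$enc1 <- make_resblock(f[1], f[2], stride = 2L)
  L$enc2 <- make_resblock(f[2], f[3], stride = 2L)
  L$enc3 <- make_resblock(f[3], f[4], stride = 2L)
  L$bridge <- make_aspp(f[4], br, variant$aspp_style)

  # decoder stages: (skip channels, decoder-in channels, stage width)
  stages <- list(c(f[3], br, f[4]), c(f[2], f[4], f[3]), c(f[1], f[3], f[2]))
  for (i in seq_along(stages)) {
    s <- stages[[i]]
    L[[paste0("att", i)]] <- make_attention(s[1], s[2], variant$attention)
    if (variant$upsample == "transpose_conv") {
      L[[paste0("up", i)]] <- make_upsample("transpose_conv", s[2], s[3])
      cat_ch <- s[3] + s[1]
    } else {
      L[[paste0("up", i)]] <- make_upsample("nearest_upsample")
      cat_ch <- s[2] + s[1]
    }
    L[[paste0("dec", i)]] <- make_resblock(cat_ch, s[3], stride = 1L)
  }
  L$aspp_out <- make_aspp(f[2], f[1], variant$aspp_style)
  L$head <- make_conv(1, 1, f[1], 1L)

  model <- new.env(parent = emptyenv())
  model$variant <- variant
  model$layers <- L
  model$seed <- seed
  model$in_channels <- as.integer(in_channels)
  model$param_list <- unlist(lapply(L, collect_params), use.names = FALSE)
  model$forward <- function(x, training = FALSE) {
    c1 <- L$stem$forward(x, training)
    c2 <- L$enc1$forward(c1, training)
    c3 <- L$enc2$forward(c2, training)
    c4 <- L$enc3$forward(c3, training)
    d <- L$bridge$forward(c4, training)
    skips <- list(c3, c2, c1)
    for (i in 1:3) {
      d <- L[[paste0("att", i)]]$forward(skips[[i]], d, training)
      d <- L[[paste0("up", i)]]$forward(d, training)
      d <- ag_concat_channels(d, skips[[i]])
      d <- L[[paste0("dec", i)]]$forward(d, training)
    }
    d <- L$aspp_out$forward(d, training)
    ag_sigmoid(L$head$forward(d))
  }
  class(model) <- "af_model"
  model
}

check_spatial <- function(h, w) {
  if (h %% 8L != 0L || w %% 8L != 0L)
    stop("spatial dims must be divisible by 8, got ", h, "x", w)
}

# Coerce matrices / lists of matrices / (N,H,W) arrays to (N,H,W,1).
as_batch <- function(images) {
  if (is.list(images)) {
    stopifnot(length(images) >= 1)
    d <- dim(images[[1]])
    arr <- array(0, dim = c(length(images), d[1], d[2], 1L))
    for (i in seq_along(images)) arr[i, , , 1] <- images[[i]]
    return(arr)
  }
  d <- dim(images)
  if (length(d) == 2L) {
    arr <- array(images, dim = c(1L, d[1], d[2], 1L))
  } else if (length(d) == 3L) {
    arr <- array(images, dim = c(d, 1L))
  } else if (length(d) == 4L) {
    arr <- images
  } else stop("cannot interpret input of dimensionality ", length(d))
  arr
}

#' Predict a segmentation
#'
#' Runs the network on one or more image slices and thresholds the sigmoid
#' probability map into a binary fluid mask.
#'
#' @param object A built (and usually trained) `"af_model"`.
#' @param newdata An `H x W` matrix, `(N, H, W)` or `(N, H, W, 1)` array, or
#'   a list of matrices; pixel values are expected in `[0, 1]` (a warning is
#'   issued otherwise) and spatial dims must be divisible by 8.
#' @param threshold Binarization threshold on the probability map.
#' @param ... Unused.
#' @return A list of class `"af_segmentation"` with `probability` and `mask`
#'   arrays of shape `(N, H, W)`.
#' @export
predict.af_model <- function(object, newdata, threshold = 0.5, ...) {
  x <- as_batch(newdata)
  d <- dim(x)
  check_spatial(d[2], d[3])
  rng <- range(x)
  if (rng[1] < 0 || rng[2] > 1)
    warning("input values outside [0, 1]; normalize slices first")
  out <- ag_value(object$forward(x, training = FALSE))
  prob <- array(out, dim = d[1:3])
  structure(list(probability = prob,
                 mask = array(as.integer(prob >= threshold), dim = d[1:3]),
                 threshold = threshold),
            class = "af_segmentation")
}

#' Fluid volume of a stacked mask
#'
#' @param masks Binary array `(n_slices, H, W)` (or a list of masks).
#' @param voxel_spacing `(dz, dy, dx)` in millimetres.
#' @return Volume in millilitres: `sum(masks) * dz*dy*dx / 1000`.
#' @export
fluid_volume <- function(masks, voxel_spacing) {
  if (is.list(masks)) masks <- as_batch(masks)[, , , 1, drop = FALSE]
  stopifnot(length(voxel_spacing) == 3L)
  sum(masks) * prod(voxel_spacing) / 1000
}

#' Slice-wise prediction of a volume
#'
#' Applies the network to every slice of a phantom (or loaded) volume and
#' integrates the predicted masks into a fluid volume.
#'
#' @param model An `"af_model"`.
#' @param volume An `"af_volume"` from [generate_volume()] / [read_volume()].
#' @param threshold Binarization threshold.
#' @param batch_size Number of slices run per forward pass.
#' @return List with `mask` `(n_slices, H, W)`, `probability`, and
#'   `volume_ml`.
#' @export
predict_volume <- function(model, volume, threshold = 0.5, batch_size = 8L) {
  stopifnot(inherits(volume, "af_volume"))
  if (is.null(volume$voxel_spacing)) stop("volume has no voxel spacing")
  imgs <- lapply(volume$slices, function(s) s$image)
  n <- length(imgs)
  d <- dim(imgs[[1]])
  prob <- array(0, dim = c(n, d[1], d[2]))
  for (start in seq(1, n, by = batch_size)) {
    ix <- start:min(start + batch_size - 1L, n)
    pr <- predict(model, imgs[ix], threshold = threshold)
    prob[ix, , ] <- pr$probability
  }
  mask <- array(as.integer(prob >= threshold), dim = dim(prob))
  list(mask = mask, probability = prob,
       volume_ml = fluid_volume(mask, volume$voxel_spacing))
}

#' @export
print.af_model <- function(x, ...) {
  v <- x$variant
  cat("AFNet-family segmentation network\n")
  cat("  variant:    ", v$name, "\n", sep = "")
  cat("  attention:  ", v$attention, "\n", sep = "")
  cat("  upsampling: ", v$upsample, "\n", sep = "")
  cat("  filters:    [", paste(v$filters, collapse = ", "), "] bridge ",
      v$bridge, "\n", sep = "")
  cat("  input size: ", v$input_size[1], "x", v$input_size[2], "x",
      x$in_channels, "\n", sep = "")
  cat("  parameters: ", format(count_parameters(x), big.mark = ","),
      " (", sprintf("%.2f", count_parameters(x) / 1e6), " M)\n", sep = "")
  invisible(x)
}

#' @export
summary.af_model <- function(object, ...) {
  rows <- lapply(names(object$layers), function(nm) {
    data.frame(layer = nm, type = object$layers[[nm]]$type,
               params = count_parameters(object$layers[[nm]]),
               stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, rows)
  df <- rbind(df, data.frame(layer = "total", type = "",
                             params = sum(df$params)))
  class(df) <- c("summary.af_model", "data.frame")
  df
}

#' Extract model weights
#'
#' @param object An `"af_model"`.
#' @param ... Unused.
#' @return Named list of parameter arrays (trainable and running statistics).
#' @export
coef.af_model <- function(object, ...) {
  ps <- object$param_list
  out <- lapply(ps, function(p) p$value)
  names(out) <- sprintf("%03d_%s", seq_along(ps),
                        vapply(ps, function(p) p$name, character(1)))
  out
}

# Copy / restore flat weight state (used to retain best-epoch weights).
get_weights <- function(model) lapply(model$param_list, function(p) p$value)
set_weights <- function(model, ws) {
  for (i in seq_along(ws)) model$param_list[[i]]$value <- ws[[i]]
  invisible(model)
}

#' Save / load a model
#'
#' Checkpoints are plain JSON: a metadata header (variant, filters, seed)
#' followed by the flat weight vectors, so they are portable and diffable.
#'
#' @param model An `"af_model"`.
#' @param path Output file (`.json`).
#' @export
save_model <- function(model, path) {
  v <- model$variant
  obj <- list(
    variant = list(name = v$name, filters = v$filters, bridge = v$bridge,
                   input_size = v$input_size, aspp_style = v$aspp_style,
                   se_ratio = v$se_ratio),
    seed = model$seed, in_channels = model$in_channels,
    n_params = count_parameters(model),
    weights = lapply(get_weights(model), as.numeric)
  )
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  v <- do.call(model_variant, c(list(name = obj$variant$name),
                                obj$variant[c("filters", "bridge",
                                              "input_size", "aspp_style",
                                              "se_ratio")]))
  model <- build_model(v, seed = obj$seed, in_channels = obj$in_channels)
  ws0 <- get_weights(model)
  ws <- obj$weights
  for (i in seq_along(ws0)) {
    w <- ws[[i]]
    dim(w) <- dim(ws0[[i]])
    ws0[[i]] <- w
  }
  set_weights(model, ws0)
  model
}
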