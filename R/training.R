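# Training protocol: patient-level 65/15/20 split, per-slice min-max
# normalization, contrast/flip augmentation, dice-loss optimization with
# Adagrad, global-norm gradient clipping, continuous exponential
# learning-rate decay and early stopping on validation mean IoU.

#' Dataset split configuration
#'
#' @param train_frac,val_frac,test_frac Fractions summing to 1.
#' @param seed Shuffle seed.
#' @param unit Split unit; `"patient"` (whole volumes, the default —
#'   prevents leakage between adjacent slices of one sequence) or
#'   `"slice"`.
#' @return List of class `"af_split_config"`.
#' @export
split_config <- function(train_frac = 0.65, val_frac = 0.15,
                         test_frac = 0.20, seed = 1L,
                         unit = c("patient", "slice")) {
  if (abs(train_frac + val_frac + test_frac - 1) > 1e-9)
    stop("fractions must sum to 1")
  structure(list(train_frac = train_frac, val_frac = val_frac,
                 test_frac = test_frac, seed = as.integer(seed),
                 unit = match.arg(unit)),
            class = "af_split_config")
}

# Largest-remainder apportionment of n units to the three fractions.
apportion <- function(n, fracs) {
  raw <- n * fracs
  base <- floor(raw)
  rem <- n - sum(base)
  if (rem > 0) {
    order_by_frac <- order(raw - base, decreasing = TRUE)
    base[order_by_frac[seq_len(rem)]] <- base[order_by_frac[seq_len(rem)]] + 1
  }
  as.integer(base)
}

#' Split a dataset into train / validation / test
#'
#' Shuffles the units (patient volumes by default, or individual slices)
#' and partitions them 65/15/20 using largest-remainder rounding, so the
#' three parts are disjoint, exhaustive and within one unit of the exact
#' fractions.  The test set is a hold-out, to be touched once.
#'
#' @param volumes List of `"af_volume"` objects (or arbitrary units when
#'   `unit = "slice"` is not needed).
#' @param config An [split_config()].
#' @return List of class `"af_split"` with elements `train`, `val`, `test`
#'   (lists of units) and `indices` (the shuffled assignment).
#' @export
split_dataset <- function(volumes, config = split_config()) {
  stopifnot(inherits(config, "af_split_config"))
  units <- volumes
  if (config$unit == "slice") {
    units <- unlist(lapply(volumes, function(v)
      if (inherits(v, "af_volume")) v$slices else list(v)), recursive = FALSE)
  }
  n <- length(units)
  if (n < 3) stop("need at least 3 units to split")
  counts <- apportion(n, c(config$train_frac, config$val_frac,
                           config$test_frac))
  perm <- with_seed(config$seed, sample.int(n))
  idx <- list(train = perm[seq_len(counts[1])],
              val = perm[counts[1] + seq_len(counts[2])],
              test = perm[counts[1] + counts[2] + seq_len(counts[3])])
  structure(list(train = units[idx$train], val = units[idx$val],
                 test = units[idx$test], indices = idx, counts = counts),
            class = "af_split")
}

#' Per-slice intensity normalization
#'
#' Linearly rescales a slice so its minimum maps to 0 and its maximum to 1;
#' constant slices map to all zeros.
#'
#' @param image Numeric matrix (or array) with finite values.
#' @return Rescaled object of the same shape.
#' @export
normalize_slice <- function(image) {
  if (any(!is.finite(image))) stop("image contains non-finite pixels")
  rng <- range(image)
  if (rng[1] == rng[2]) return(image * 0)
  (image - rng[1]) / (rng[2] - rng[1])
}

#' Augmentation configuration
#'
#' @param contrast_range Half-open interval the contrast factor is drawn
#'   from, uniformly.
#' @param flip_horizontal,flip_vertical Enable the respective random flips
#'   (applied with probability 1/2, identically to image and mask).
#' @return List of class `"af_augment_config"`.
#' @export
augment_config <- function(contrast_range = c(0.4, 0.6),
                           flip_horizontal = TRUE, flip_vertical = TRUE) {
  stopifnot(length(contrast_range) == 2, contrast_range[1] < contrast_range[2])
  structure(list(contrast_range = contrast_range,
                 flip_horizontal = isTRUE(flip_horizontal),
                 flip_vertical = isTRUE(flip_vertical)),
            class = "af_augment_config")
}

#' Randomly augment a sample
#'
#' Contrast is adjusted as `mean(x) + factor * (x - mean(x))` with `factor`
#' drawn uniformly from `contrast_range`, then clipped to `[0, 1]`; flips
#' are applied identically to image and mask, so the mask stays binary with
#' unchanged area.  Uses the current RNG stream.
#'
#' @param sample An `"af_sample"` (or list with `image` and `mask`).
#' @param config An [augment_config()].
#' @return The augmented sample; the applied factor and flips are recorded
#'   in `sample$meta$augment`.
#' @export
augment_sample <- function(sample, config = augment_config()) {
  img <- sample$image; msk <- sample$mask
  fac <- stats::runif(1, config$contrast_range[1], config$contrast_range[2])
  img <- mean(img) + fac * (img - mean(img))
  img <- pmin(pmax(img, 0), 1)
  fh <- config$flip_horizontal && stats::runif(1) < 0.5
  fv <- config$flip_vertical && stats::runif(1) < 0.5
  if (fh) { img <- img[, ncol(img):1]; msk <- msk[, ncol(msk):1] }
  if (fv) { img <- img[nrow(img):1, ]; msk <- msk[nrow(msk):1, ] }
  sample$image <- img
  sample$mask <- msk
  sample$meta$augment <- list(factor = fac, flip_h = fh, flip_v = fv)
  sample
}

#' Training configuration
#'
#' The reference protocol: Adagrad at learning rate 0.1 with global-norm
#' gradient clipping, exponential decay (rate 0.96 per 10,000 steps,
#' continuous exponent), dice loss, batches of 8, at most 200 epochs, early
#' stopping on validation mean IoU with patience 10 and baseline 0.75.
#'
#' @param optimizer `"adagrad"` (the protocol) or `"adam"`.
#' @param learning_rate Initial learning rate.
#' @param gradient_clip_norm Global-norm clipping threshold.
#' @param decay_rate,decay_steps Exponential decay: the learning rate at
#'   step `s` is `learning_rate * decay_rate^(s / decay_steps)`.
#' @param max_epochs,batch_size Epoch cap and batch size.
#' @param patience,baseline Early-stopping patience (epochs) and metric
#'   baseline.
#' @param target_loss,target_miou Optional convergence shortcuts: stop once
#'   the epoch training loss falls below `target_loss` and the monitored
#'   mean IoU exceeds `target_miou` (whichever of the two are set; used by
#'   capacity smoke tests).
#' @return List of class `"af_train_config"`.
#' @export
train_config <- function(optimizer = c("adagrad", "adam"),
                         learning_rate = 0.1, gradient_clip_norm = 1.0,
                         decay_rate = 0.96, decay_steps = 10000L,
                         max_epochs = 200L, batch_size = 8L,
                         patience = 10L, baseline = 0.75,
                         target_loss = NULL, target_miou = NULL) {
  structure(list(optimizer = match.arg(optimizer),
                 learning_rate = learning_rate,
                 gradient_clip_norm = gradient_clip_norm,
                 decay_rate = decay_rate, decay_steps = as.integer(decay_steps),
                 max_epochs = as.integer(max_epochs),
                 batch_size = as.integer(batch_size),
                 early_stop_monitor = "mIoU",
                 patience = as.integer(patience), baseline = baseline,
                 loss = "dice", target_loss = target_loss,
                 target_miou = target_miou),
            class = "af_train_config")
}

#' Learning rate at an optimizer step
#'
#' @param step Zero-based global step count.
#' @param learning_rate Initial rate.
#' @param decay_rate,decay_steps Exponential decay constants.
#' @return `learning_rate * decay_rate^(step / decay_steps)`.
#' @export
lr_at_step <- function(step, learning_rate = 0.1, decay_rate = 0.96,
                       decay_steps = 10000L) {
  learning_rate * decay_rate^(step / decay_steps)
}

#' Early-stopping decision rule
#'
#' An epoch improves when its monitored value strictly exceeds the best of
#' (all previous epochs, the baseline).  Training stops once `patience`
#' consecutive epochs fail to improve; the rule returns the 1-based epoch at
#' which training halts, or `NA` if the history never triggers a stop.
#'
#' @param history Numeric vector of per-epoch monitored values (mean IoU).
#' @param patience Consecutive non-improving epochs tolerated.
#' @param baseline Initial best value that must be beaten.
#' @return Stopping epoch or `NA_integer_`.
#' @export
early_stopping_decision <- function(history, patience = 10L, baseline = 0.75) {
  if (length(history) == 0) stop("history must be non-empty")
  best <- baseline
  wait <- 0L
  for (i in seq_along(history)) {
    if (history[i] > best) {
      best <- history[i]
      wait <- 0L
    } else {
      wait <- wait + 1L
      if (wait >= patience) return(i)
    }
  }
  NA_integer_
}

# ---- optimizer -------------------------------------------------------------

# Adagrad with TensorFlow's 0.1 initial accumulator; Adam with the usual
# (0.9, 0.999) moments.  State lives alongside the parameter list.
optimizer_new <- function(params, config) {
  st <- new.env(parent = emptyenv())
  st$params <- Filter(function(p) isTRUE(p$trainable), params)
  st$kind <- config$optimizer
  st$acc <- lapply(st$params, function(p) array(0.1, dim = dim(p$value) %||% length(p$value)))
  if (st$kind == "adam") {
    st$m <- lapply(st$params, function(p) p$value * 0)
    st$v <- lapply(st$params, function(p) p$value * 0)
    st$t <- 0
  }
  st
}

`%||%` <- function(a, b) if (is.null(a)) b else a

optimizer_step <- function(st, lr, clip_norm) {
  grads <- lapply(st$params, function(p) p$grad %||% (p$value * 0))
  gn <- sqrt(sum(vapply(grads, function(g) sum(g^2), numeric(1))))
  if (!is.finite(gn)) stop("divergence: non-finite gradient norm")
  if (!is.null(clip_norm) && gn > clip_norm)
    grads <- lapply(grads, function(g) g * (clip_norm / gn))
  if (st$kind == "adagrad") {
    for (i in seq_along(st$params)) {
      g <- grads[[i]]
      st$acc[[i]] <- st$acc[[i]] + g^2
      st$params[[i]]$value <- st$params[[i]]$value -
        lr * g / (sqrt(st$acc[[i]]) + 1e-7)
    }
  } else {
    st$t <- st$t + 1
    b1 <- 0.9; b2 <- 0.999
    for (i in seq_along(st$params)) {
      g <- grads[[i]]
      st$m[[i]] <- b1 * st$m[[i]] + (1 - b1) * g
      st$v[[i]] <- b2 * st$v[[i]] + (1 - b2) * g^2
      mh <- st$m[[i]] / (1 - b1^st$t)
      vh <- st$v[[i]] / (1 - b2^st$t)
      st$params[[i]]$value <- st$params[[i]]$value -
        lr * mh / (sqrt(vh) + 1e-7)
    }
  }
  gn
}

zero_grads <- function(params) {
  for (p in params) p$grad <- NULL
  invisible(NULL)
}

# Flatten whatever the caller passes (volumes, samples, split parts) into a
# list of image/mask samples.
as_samples <- function(x) {
  if (inherits(x, "af_sample")) return(list(x))
  if (inherits(x, "af_volume")) return(x$slices)
  if (is.list(x)) return(unlist(lapply(x, as_samples), recursive = FALSE))
  stop("cannot interpret training data of class ", paste(class(x), collapse = "/"))
}

#' Train a segmentation network
#'
#' Minimizes the soft dice loss over the training samples with the
#' configured optimizer and schedule, evaluating validation mean IoU after
#' every epoch, retaining the weights of the best validation epoch and
#' stopping early per the patience/baseline rule.
#'
#' @param model An `"af_model"` from [build_model()] (modified in place and
#'   returned inside the fit object).
#' @param train_data,val_data Volumes or samples (anything coercible by the
#'   generator types).  `val_data = NULL` evaluates mean IoU on the
#'   training samples instead.
#' @param config An [train_config()].
#' @param augment An [augment_config()], or `NULL` to disable augmentation.
#' @param seed Seed for shuffling, augmentation draws and batch order.
#' @param threshold Binarization threshold for the mean-IoU monitor.
#' @param verbose Print a line per epoch.
#' @return An object of class `"af_fit"`: the trained model, a history data
#'   frame (`epoch`, `lr`, `loss`, `val_miou`), the best epoch and the
#'   stopping epoch (or NA).
#' @export
train_model <- function(model, train_data, val_data = NULL,
                        config = train_config(), augment = augment_config(),
                        seed = 1L, threshold = 0.5, verbose = FALSE) {
  stopifnot(inherits(model, "af_model"), inherits(config, "af_train_config"))
  train_samples <- as_samples(train_data)
  val_samples <- if (is.null(val_data)) train_samples else as_samples(val_data)
  if (length(train_samples) == 0) stop("empty training set")

  opt <- optimizer_new(model$param_list, config)
  n <- length(train_samples)
  step <- 0L
  history <- data.frame(epoch = integer(), lr = numeric(), loss = numeric(),
                        val_miou = numeric())
  best_miou <- -Inf
  best_weights <- get_weights(model)
  best_epoch <- NA_integer_
  stopped_at <- NA_integer_

  eval_miou <- function(samples) {
    ious <- vapply(samples, function(s) {
      pr <- predict(model, s$image, threshold = threshold)
      jaccard(confusion_counts(pr$mask[1, , ], s$mask))
    }, numeric(1))
    mean(ious)
  }

  old_seed <- get0(".Random.seed", globalenv(), inherits = FALSE)
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(seed)

  for (epoch in seq_len(config$max_epochs)) {
    ord <- sample.int(n)
    epoch_loss <- 0
    nb <- 0L
    for (start in seq(1, n, by = config$batch_size)) {
      ix <- ord[start:min(start + config$batch_size - 1L, n)]
      batch <- train_samples[ix]
      if (!is.null(augment))
        batch <- lapply(batch, augment_sample, config = augment)
      x <- as_batch(lapply(batch, function(s) s$image))
      y <- as_batch(lapply(batch, function(s) s$mask))
      lr <- lr_at_step(step, config$learning_rate, config$decay_rate,
                       config$decay_steps)
      zero_grads(model$param_list)
      ag_tape_begin()
      loss <- ag_dice_loss(model$forward(x, training = TRUE), y)
      lv <- ag_value(loss)
      if (!is.finite(lv)) {
        ag_tape_end()
        stop("divergence: non-finite dice loss at epoch ", epoch)
      }
      ag_backward(loss)
      ag_tape_end()
      optimizer_step(opt, lr, config$gradient_clip_norm)
      epoch_loss <- epoch_loss + lv
      nb <- nb + 1L
      step <- step + 1L
    }
    epoch_loss <- epoch_loss / nb
    vm <- eval_miou(val_samples)
    history <- rbind(history,
                     data.frame(epoch = epoch,
                                lr = lr_at_step(step - 1L, config$learning_rate,
                                                config$decay_rate,
                                                config$decay_steps),
                                loss = epoch_loss, val_miou = vm))
    if (vm > best_miou) {
      best_miou <- vm
      best_weights <- get_weights(model)
      best_epoch <- epoch
    }
    if (verbose)
      message(sprintf("epoch %3d  loss %.4f  val mIoU %.4f", epoch,
                      epoch_loss, vm))
    if ((!is.null(config$target_loss) || !is.null(config$target_miou)) &&
        (is.null(config$target_loss) || epoch_loss < config$target_loss) &&
        (is.null(config$target_miou) || vm > config$target_miou)) break
    se <- early_stopping_decision(history$val_miou, config$patience,
                                  config$baseline)
    if (!is.na(se)) { stopped_at <- se; break }
  }

  final_weights <- get_weights(model)
  structure(list(model = model, history = history, best_epoch = best_epoch,
                 best_val_miou = best_miou, stopped_at = stopped_at,
                 config = config, seed = seed,
                 best_weights = best_weights, final_weights = final_weights),
            class = "af_fit")
}

#' Restore a fit's best-epoch weights into its model
#'
#' @param fit An `"af_fit"`.
#' @param which `"best"` (highest validation mean IoU) or `"final"`.
#' @return The model, with the requested weights loaded.
#' @export
restore_weights <- function(fit, which = c("best", "final")) {
  which <- match.arg(which)
  set_weights(fit$model,
              if (which == "best") fit$best_weights else fit$final_weights)
  fit$model
}

#' @export
print.af_fit <- function(x, ...) {
  h <- x$history
  cat("trained", x$model$variant$name, "for", nrow(h), "epoch(s)\n")
  cat(sprintf("  final loss %.4f, best val mIoU %.4f at epoch %s\n",
              h$loss[nrow(h)], x$best_val_miou, x$best_epoch))
  if (!is.na(x$stopped_at)) cat("  early-stopped at epoch", x$stopped_at, "\n")
  invisible(x)
}

#' @export
summary.af_fit <- function(object, ...) {
  list(history = object$history, best_epoch = object$best_epoch,
       best_val_miou = object$best_val_miou, stopped_at = object$stopped_at)
}

#' @export
plot.af_fit <- function(x, ...) {
  h <- x$history
  graphics::par(mfrow = c(1, 2))
  graphics::plot(h$epoch, h$loss, type = "l", xlab = "epoch",
                 ylab = "dice loss", main = "training loss", ...)
  graphics::plot(h$epoch, h$val_miou, type = "l", xlab = "epoch",
                 ylab = "mean IoU", main = "validation mIoU", ...)
  invisible(x)
}

#' @export
predict.af_fit <- function(object, newdata, ...) {
  predict(object$model, newdata, ...)
}

#' Residuals of a segmentation fit
#'
#' Per-pixel difference between predicted probability and ground truth on
#' given samples; useful to inspect systematic over-/under-segmentation.
#'
#' @param object An `"af_fit"`.
#' @param data Samples or volumes to evaluate on.
#' @param ... Unused.
#' @return List of matrices `probability - truth`, one per sample.
#' @export
residuals.af_fit <- function(object, data, ...) {
  samples <- as_samples(data)
  lapply(samples, function(s) {
    pr <- predict(object$model, s$image)
    pr$probability[1, , ] - s$mask
  })
}
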