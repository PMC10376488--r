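# Segmentation metric suite: pixel confusion tallies and the overlap
# metrics derived from them (Jaccard/IoU, Dice, precision, recall), the
# differentiable soft dice loss, dataset-level mean IoU and the paired
# comparison of training runs.
#
# Conventions: the positive class is amniotic fluid (label 1).  When a
# metric's denominator is empty -- both masks empty for Jaccard/Dice, no
# predicted positives for precision, no true positives for recall -- the
# metric is defined as 1, so all-background slices (common at volume edges)
# count as perfect agreement rather than zeroing a dataset mean.

check_binary <- function(m, what) {
  v <- as.vector(m)
  if (!all(v == 0 | v == 1))
    stop(what, " must be strictly binary (0/1)")
  invisible(TRUE)
}

#' Pixel confusion counts
#'
#' Tallies true/false positives/negatives between a predicted and a ground
#' truth binary mask.
#'
#' @param pred,truth Binary masks of identical shape.
#' @return A list of class `"af_confusion"` with integer fields `TP`, `FP`,
#'   `FN`, `TN`.
#' @export
confusion_counts <- function(pred, truth) {
  if (!identical(dim(pred), dim(truth)) || length(pred) != length(truth))
    stop("pred and truth must have identical shape")
  check_binary(pred, "pred"); check_binary(truth, "truth")
  p <- as.vector(pred) == 1; t <- as.vector(truth) == 1
  structure(list(TP = sum(p & t), FP = sum(p & !t),
                 FN = sum(!p & t), TN = sum(!p & !t)),
            class = "af_confusion")
}

as_confusion <- function(c) {
  if (inherits(c, "af_confusion")) return(c)
  stopifnot(all(c(c$TP, c$FP, c$FN, c$TN) >= 0))
  structure(c[c("TP", "FP", "FN", "TN")], class = "af_confusion")
}

#' Overlap metrics from confusion counts
#'
#' `jaccard()` is `TP / (TP + FP + FN)` (intersection over union);
#' `dice()` is `2 TP / (2 TP + FP + FN)`, identically `2 J / (J + 1)`;
#' `precision()` is `TP / (TP + FP)`; `recall()` (true positive rate) is
#' `TP / (TP + FN)`.  Empty denominators yield 1 (see package conventions).
#'
#' @param c An `"af_confusion"` (or a list with fields `TP,FP,FN,TN`).
#' @return A number in `[0, 1]`.
#' @export
jaccard <- function(c) {
  c <- as_confusion(c)
  den <- c$TP + c$FP + c$FN
  if (den == 0) return(1)
  c$TP / den
}

#' @rdname jaccard
#' @export
dice <- function(c) {
  c <- as_confusion(c)
  den <- 2 * c$TP + c$FP + c$FN
  if (den == 0) return(1)
  2 * c$TP / den
}

#' @rdname jaccard
#' @export
precision <- function(c) {
  c <- as_confusion(c)
  if (c$TP + c$FP == 0) return(1)
  c$TP / (c$TP + c$FP)
}

#' @rdname jaccard
#' @export
recall <- function(c) {
  c <- as_confusion(c)
  if (c$TP + c$FN == 0) return(1)
  c$TP / (c$TP + c$FN)
}

#' Soft dice loss
#'
#' `1 - (2 sum(p*t) + eps) / (sum(p) + sum(t) + eps)` with raw probabilities
#' in the intersection term, so the loss is differentiable; on binary
#' predictions it equals `1 - dice(confusion_counts(p, t))` up to the
#' smoothing term.
#'
#' @param prob Predicted probabilities in `[0, 1]`, same shape as `truth`.
#' @param truth Binary ground truth mask.
#' @param smooth Smoothing constant added to numerator and denominator.
#' @return Loss in `[0, 1]`.
#' @export
dice_loss <- function(prob, truth, smooth = 1e-6) {
  if (length(prob) != length(truth))
    stop("prob and truth must have identical shape")
  if (min(prob) < 0 || max(prob) > 1)
    stop("prob must lie in [0, 1]")
  p <- as.numeric(prob); t <- as.numeric(truth)
  1 - (2 * sum(p * t) + smooth) / (sum(p) + sum(t) + smooth)
}

#' Dataset mean IoU
#'
#' Unweighted mean (and standard deviation) of per-image Jaccard indices.
#'
#' @param ious Numeric vector of per-image IoU values.
#' @return List with `mean`, `sd` (NA for a single image) and `n`.
#' @export
mean_iou <- function(ious) {
  if (length(ious) == 0) stop("empty IoU list")
  list(mean = mean(ious), sd = stats::sd(ious), n = length(ious))
}

#' Per-image metric report
#'
#' Convenience wrapper computing the full metric suite over matched lists
#' of predicted and truth masks.
#'
#' @param preds,truths Lists of binary masks (or 3-D arrays, slice-first).
#' @return A list of class `"af_metric_report"`: per-image data frame plus
#'   aggregate fields `miou`, `miou_sd`, `dice`, `precision`, `recall`,
#'   `dice_loss` and `n_images`.
#' @export
metric_report <- function(preds, truths) {
  if (is.array(preds) && length(dim(preds)) == 3)
    preds <- lapply(seq_len(dim(preds)[1]), function(i) preds[i, , ])
  if (is.array(truths) && length(dim(truths)) == 3)
    truths <- lapply(seq_len(dim(truths)[1]), function(i) truths[i, , ])
  stopifnot(length(preds) == length(truths), length(preds) >= 1)
  per <- do.call(rbind, lapply(seq_along(preds), function(i) {
    cc <- confusion_counts(preds[[i]], truths[[i]])
    data.frame(image = i, jaccard = jaccard(cc), dice = dice(cc),
               precision = precision(cc), recall = recall(cc))
  }))
  mi <- mean_iou(per$jaccard)
  structure(list(per_image = per, miou = mi$mean, miou_sd = mi$sd,
                 dice = mean(per$dice), precision = mean(per$precision),
                 recall = mean(per$recall),
                 dice_loss = 1 - mean(per$dice), n_images = mi$n),
            class = "af_metric_report")
}

#' @export
print.af_metric_report <- function(x, ...) {
  cat(sprintf("segmentation metrics over %d image(s):\n", x$n_images))
  cat(sprintf("  mIoU      %.4f +/- %s\n", x$miou,
              ifelse(is.na(x$miou_sd), "NA", sprintf("%.4f", x$miou_sd))))
  cat(sprintf("  dice      %.4f\n", x$dice))
  cat(sprintf("  precision %.4f\n", x$precision))
  cat(sprintf("  recall    %.4f\n", x$recall))
  invisible(x)
}

#' Paired comparison of model runs
#'
#' Two-sided Student's t-test on per-run mean-IoU values of two models,
#' paired by run (same data split, different weight seeds).  Degenerate
#' zero-variance differences return p = 1 when the means agree and p = 0
#' otherwise.
#'
#' @param a,b Numeric vectors of per-run mIoU values.
#' @param paired Pair runs by position (requires equal lengths).
#' @return List with `p_value`, `statistic`, `df` and `mean_diff`.
#' @export
compare_runs <- function(a, b, paired = TRUE) {
  if (paired && length(a) != length(b))
    stop("paired comparison requires equally many runs")
  if (length(a) < 2 || length(b) < 2) stop("need at least two runs per model")
  if (paired) {
    d <- a - b
    if (stats::sd(d) == 0) {
      return(list(p_value = if (mean(d) == 0) 1 else 0,
                  statistic = NA_real_, df = length(d) - 1,
                  mean_diff = mean(d)))
    }
  } else if (stats::sd(a) == 0 && stats::sd(b) == 0) {
    return(list(p_value = if (mean(a) == mean(b)) 1 else 0,
                statistic = NA_real_, df = NA_real_,
                mean_diff = mean(a) - mean(b)))
  }
  tt <- stats::t.test(a, b, paired = paired)
  list(p_value = unname(tt$p.value), statistic = unname(tt$statistic),
       df = unname(tt$parameter), mean_diff = unname(mean(a) - mean(b)))
}
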