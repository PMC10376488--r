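# Ablation harness: repeated seeded training runs of the three variants on
# one fixed dataset split, summarized as mean +/- sd test mIoU per variant
# with paired t-tests between variants.

#' Run the variant ablation study
#'
#' Generates (or accepts) a phantom dataset, fixes one patient-level
#' 65/15/20 split, then trains every variant `n_runs` times with different
#' weight-initialization seeds and compares the resulting per-run test mean
#' IoU values by paired t-tests.
#'
#' @param n_runs Training runs per variant.
#' @param variants Character vector of variant names.
#' @param data Optional list of `"af_volume"`; generated from
#'   `phantom` when `NULL`.
#' @param phantom An [phantom_config()] for generated data.
#' @param n_patients,n_slices_range Dataset size when generating.
#' @param filters,bridge Network widths for the trained models (desk-scale
#'   defaults; the calibrated widths of [model_variant()] are intended for
#'   full-resolution work).
#' @param train An [train_config()]; lower `max_epochs` for desk scale.
#' @param seed Master seed: fixes the dataset, the split and the per-run
#'   weight seeds.
#' @param verbose Print progress lines.
#' @return An `"af_ablation"`: `table` (variant, mean/sd mIoU, parameter
#'   count), `runs` (per-run mIoU matrix), `tests` (pairwise paired
#'   t-tests).
#' @export
ablation_study <- function(n_runs = 3L,
                           variants = c("resunetpp", "afnet_noT", "afnet"),
                           data = NULL, phantom = NULL,
                           n_patients = 6L, n_slices_range = c(3L, 5L),
                           filters = c(4L, 8L, 16L, 32L), bridge = 64L,
                           train = train_config(max_epochs = 5L),
                           seed = 1L, verbose = FALSE) {
  if (is.null(phantom))
    phantom <- phantom_config(image_size = 32L, noise_sigma = 0.02,
                              gradient_strength = 0, seed = seed)
  if (is.null(data))
    data <- generate_dataset(phantom, n_patients,
                             n_slices_range = n_slices_range, seed = seed)
  split <- split_dataset(data, split_config(seed = seed))
  d <- dim(split$train[[1]]$slices[[1]]$image)
  run_seeds <- derive_seeds(seed + 7L, n_runs)

  runs <- matrix(NA_real_, n_runs, length(variants),
                 dimnames = list(NULL, variants))
  params <- integer(length(variants))
  for (vi in seq_along(variants)) {
    v <- model_variant(variants[vi], filters = filters, bridge = bridge,
                       input_size = d)
    for (r in seq_len(n_runs)) {
      model <- build_model(v, seed = run_seeds[r])
      fit <- train_model(model, split$train, split$val, config = train,
                         seed = run_seeds[r], verbose = FALSE)
      model <- restore_weights(fit, "best")
      test_samples <- as_samples(split$test)
      ious <- vapply(test_samples, function(s) {
        pr <- predict(model, s$image)
        jaccard(confusion_counts(pr$mask[1, , ], s$mask))
      }, numeric(1))
      runs[r, vi] <- mean(ious)
      if (verbose)
        message(sprintf("%s run %d/%d: test mIoU %.4f", variants[vi], r,
                        n_runs, runs[r, vi]))
    }
    params[vi] <- as.integer(count_parameters(build_model(v, seed = run_seeds[1])))
  }

  table <- data.frame(variant = variants,
                      miou_mean = colMeans(runs),
                      miou_sd = apply(runs, 2, stats::sd),
                      parameters = params,
                      stringsAsFactors = FALSE)
  tests <- list()
  if (length(variants) >= 2 && n_runs >= 2) {
    cmb <- utils::combn(seq_along(variants), 2)
    for (k in seq_len(ncol(cmb))) {
      i <- cmb[1, k]; j <- cmb[2, k]
      nm <- paste(variants[i], "vs", variants[j])
      tests[[nm]] <- compare_runs(runs[, i], runs[, j], paired = TRUE)
    }
  }
  structure(list(table = table, runs = runs, tests = tests, seed = seed),
            class = "af_ablation")
}

#' @export
print.af_ablation <- function(x, ...) {
  cat("ablation over", nrow(x$runs), "paired runs per variant:\n")
  tb <- x$table
  for (i in seq_len(nrow(tb)))
    cat(sprintf("  %-10s mIoU %.4f +/- %.4f   %s params\n", tb$variant[i],
                tb$miou_mean[i], tb$miou_sd[i],
                format(tb$parameters[i], big.mark = ",")))
  for (nm in names(x$tests))
    cat(sprintf("  %-28s p = %.4f\n", nm, x$tests[[nm]]$p_value))
  invisible(x)
}
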