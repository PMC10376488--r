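# Training protocol: splitting, normalization, augmentation, the learning
# rate schedule, the early-stopping rule and a small end-to-end smoke run.

test_that("the 65/15/20 split apportions units by largest remainder", {
  expect_identical(afnet:::apportion(45, c(0.65, 0.15, 0.20)), c(29L, 7L, 9L))
  expect_identical(afnet:::apportion(20, c(0.65, 0.15, 0.20)), c(13L, 3L, 4L))
  # n = 3: remainders are 0.95 (train), 0.45 (val), 0.60 (test), so the two
  # leftover units go to train and test
  expect_identical(afnet:::apportion(3, c(0.65, 0.15, 0.20)), c(2L, 0L, 1L))
})

test_that("splits are disjoint, exhaustive and deterministic per seed", {
  units <- as.list(1:20)
  for (seed in c(1L, 7L, 99L)) {
    sp <- split_dataset(units, split_config(seed = seed))
    ix <- sp$indices
    expect_length(c(ix$train, ix$val, ix$test), 20)
    expect_identical(sort(c(ix$train, ix$val, ix$test)), 1:20)
    expect_length(intersect(ix$train, ix$val), 0)
    expect_length(intersect(ix$train, ix$test), 0)
    expect_length(intersect(ix$val, ix$test), 0)
    sp2 <- split_dataset(units, split_config(seed = seed))
    expect_identical(sp$indices, sp2$indices)
  }
  expect_identical(split_dataset(units, split_config(seed = 1))$counts,
                   c(13L, 3L, 4L))
  expect_error(split_dataset(as.list(1:2)), "at least 3")
  expect_error(split_config(train_frac = 0.5, val_frac = 0.1, test_frac = 0.2),
               "sum to 1")
})

test_that("slice normalization rescales to [0, 1] with stated conventions", {
  expect_equal(normalize_slice(c(0, 127.5, 255)), c(0, 0.5, 1))
  x <- matrix(runif(16), 4, 4)
  x[1] <- 0; x[16] <- 1
  expect_equal(normalize_slice(x), x)
  expect_equal(normalize_slice(matrix(3.7, 2, 2)), matrix(0, 2, 2))
  expect_error(normalize_slice(c(1, NA)), "finite")
})

test_that("contrast augmentation scales deviations by the drawn factor", {
  img <- matrix(runif(64 * 64, 0.3, 0.7), 64, 64)   # margin: no clipping
  s <- structure(list(image = img, mask = matrix(0L, 64, 64), meta = list()),
                 class = "af_sample")
  cfg <- augment_config(flip_horizontal = FALSE, flip_vertical = FALSE)
  set.seed(41)
  out <- augment_sample(s, cfg)
  f <- out$meta$augment$factor
  expect_true(f >= 0.4 && f < 0.6)
  expect_equal(sd(out$image) / sd(img), f, tolerance = 1e-12)
  expect_equal(mean(out$image), mean(img), tolerance = 1e-12)
})

test_that("flips are involutive and preserve mask area and binarity", {
  cfg0 <- phantom_config(image_size = 32, noise_sigma = 0, seed = 3)
  s <- generate_slice(cfg0)
  # double horizontal flip is the identity
  expect_identical(s$image[, 32:1][, 32:1], s$image)
  set.seed(42)
  for (i in 1:20) {
    out <- augment_sample(s, augment_config())
    expect_identical(sum(out$mask), sum(s$mask))
    expect_true(all(out$mask %in% c(0L, 1L)))
    expect_true(all(out$image >= 0 & out$image <= 1))
    aug <- out$meta$augment
    if (aug$flip_h || aug$flip_v) {
      m <- s$mask
      if (aug$flip_h) m <- m[, ncol(m):1]
      if (aug$flip_v) m <- m[nrow(m):1, ]
      expect_identical(out$mask, m)
    }
  }
})

test_that("the learning rate follows its continuous exponential closed form", {
  expect_equal(lr_at_step(0), 0.1)
  expect_equal(lr_at_step(10000), 0.1 * 0.96)
  steps <- c(1, 137, 2500, 10000, 50000)
  expect_equal(lr_at_step(steps), 0.1 * 0.96^(steps / 10000))
  expect_equal(lr_at_step(5000, learning_rate = 0.2, decay_rate = 0.5,
                          decay_steps = 1000), 0.2 * 0.5^5)
})

test_that("early stopping follows the patience/baseline rule", {
  # never beats the 0.75 baseline: stops exactly at the patience
  expect_identical(early_stopping_decision(rep(0.74, 12), 10, 0.75), 10L)
  # increasing series that crosses the baseline early: never stops
  expect_identical(early_stopping_decision(seq(0.70, 0.99, by = 0.01), 10, 0.75),
                   NA_integer_)
  # beats the baseline then plateaus: stops 10 epochs after the peak
  hist <- c(0.76, 0.80, 0.85, rep(0.85, 10))
  expect_identical(early_stopping_decision(hist, 10, 0.75), 13L)
  # improvement must be strict
  expect_identical(early_stopping_decision(rep(0.80, 11), 10, 0.75), 11L)
  expect_error(early_stopping_decision(numeric(0)), "non-empty")
})

test_that("a short training run decreases the dice loss deterministically", {
  cfg <- phantom_config(image_size = 32, n_fluid_blobs = 1, n_confounders = 0,
                        noise_sigma = 0, gradient_strength = 0, seed = 13)
  samples <- lapply(1:4, function(i) generate_slice(cfg, seed = 50 + i))
  run <- function() {
    m <- build_model(model_variant("afnet", filters = c(2, 4, 8, 16),
                                   bridge = 32, input_size = c(32, 32)),
                     seed = 2)
    train_model(m, samples, config = train_config(max_epochs = 4, baseline = 2,
                                                  patience = 100),
                augment = NULL, seed = 2)
  }
  fit <- run()
  h <- fit$history
  expect_identical(nrow(h), 4L)
  expect_lt(h$loss[4], h$loss[1])
  expect_equal(h$lr, lr_at_step(0:3), tolerance = 1e-12)
  # rerunning with the same seeds reproduces the history exactly
  expect_equal(run()$history, h, tolerance = 1e-12)
})

test_that("training histories feed the early-stopping rule", {
  cfg <- phantom_config(image_size = 32, n_fluid_blobs = 1, n_confounders = 0,
                        noise_sigma = 0, gradient_strength = 0, seed = 14)
  samples <- lapply(1:3, function(i) generate_slice(cfg, seed = 60 + i))
  m <- build_model(model_variant("resunetpp", filters = c(2, 4, 8, 16),
                                 bridge = 32, input_size = c(32, 32)),
                   seed = 3)
  # an untrained network stays below the 0.75 baseline, so patience-2
  # stopping must trigger at epoch 2
  fit <- train_model(m, samples, config = train_config(max_epochs = 10,
                                                       patience = 2),
                     augment = NULL, seed = 3)
  expect_identical(fit$stopped_at, 2L)
  expect_identical(nrow(fit$history), 2L)
})

test_that("median validation mIoU improves from first epoch to best epoch", {
  cfg <- phantom_config(image_size = 32, n_fluid_blobs = 2, n_confounders = 0,
                        noise_sigma = 0, gradient_strength = 0, seed = 15)
  samples <- lapply(1:6, function(i) generate_slice(cfg, seed = 70 + i))
  gains <- vapply(1:3, function(sd) {
    m <- build_model(model_variant("afnet", filters = c(2, 4, 8, 16),
                                   bridge = 32, input_size = c(32, 32)),
                     seed = sd)
    fit <- train_model(m, samples, config = train_config(max_epochs = 8,
                                                         baseline = 2,
                                                         patience = 100),
                       augment = NULL, seed = sd)
    max(fit$history$val_miou) - fit$history$val_miou[1]
  }, numeric(1))
  expect_gt(median(gains), 0)
})
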