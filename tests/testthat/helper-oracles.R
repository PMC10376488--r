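# Independent oracles: straightforward (slow) reference implementations the
# package code is checked against.

# Direct convolution with TF-style "same" padding, plain R loops.
brute_conv2d <- function(x, w, b, stride = 1, dil = 1) {
  d <- dim(x); wd <- dim(w)
  ke_h <- (wd[1] - 1) * dil + 1; ke_w <- (wd[2] - 1) * dil + 1
  oh <- ceiling(d[2] / stride); ow <- ceiling(d[3] / stride)
  ph <- max((oh - 1) * stride + ke_h - d[2], 0) %/% 2
  pw <- max((ow - 1) * stride + ke_w - d[3], 0) %/% 2
  out <- array(0, c(d[1], oh, ow, wd[4]))
  for (n in seq_len(d[1])) for (co in seq_len(wd[4]))
    for (i in seq_len(oh)) for (j in seq_len(ow)) {
      acc <- b[co]
      for (ki in seq_len(wd[1])) for (kj in seq_len(wd[2]))
        for (ci in seq_len(wd[3])) {
          ih <- (i - 1) * stride - ph + (ki - 1) * dil + 1
          iw <- (j - 1) * stride - pw + (kj - 1) * dil + 1
          if (ih >= 1 && ih <= d[2] && iw >= 1 && iw <= d[3])
            acc <- acc + x[n, ih, iw, ci] * w[ki, kj, ci, co]
        }
      out[n, i, j, co] <- acc
    }
  out
}

# Per-pixel rasterization of a harmonically perturbed ellipse, written as an
# explicit double loop (independent of the vectorized generator path).
oracle_blob_mask <- function(blob, size) {
  m <- matrix(FALSE, size, size)
  for (yy in seq_len(size)) for (xx in seq_len(size)) {
    u <- (xx - blob$cx) * cos(blob$rot) + (yy - blob$cy) * sin(blob$rot)
    v <- -(xx - blob$cx) * sin(blob$rot) + (yy - blob$cy) * cos(blob$rot)
    r <- sqrt((u / blob$a)^2 + (v / blob$b)^2)
    th <- atan2(v, u)
    lim <- 1
    for (k in seq_along(blob$amp))
      lim <- lim + blob$amp[k] * sin((k + 1) * th + blob$phase[k])
    m[yy, xx] <- r <= lim
  }
  m
}

# Confusion tallies by naive enumeration.
oracle_confusion <- function(pred, truth) {
  tp <- 0L; fp <- 0L; fn <- 0L; tn <- 0L
  for (i in seq_along(pred)) {
    if (pred[i] == 1 && truth[i] == 1) tp <- tp + 1L
    else if (pred[i] == 1) fp <- fp + 1L
    else if (truth[i] == 1) fn <- fn + 1L
    else tn <- tn + 1L
  }
  list(TP = tp, FP = fp, FN = fn, TN = tn)
}

# Finite-difference gradient of `fn` (scalar) w.r.t. one parameter entry.
fd_grad <- function(fn, param, i, eps = 1e-5) {
  v0 <- param$value[i]
  param$value[i] <- v0 + eps
  lp <- fn()
  param$value[i] <- v0 - eps
  lm <- fn()
  param$value[i] <- v0
  (lp - lm) / (2 * eps)
}

# Small deterministic phantom training set shared by smoke tests.
make_overfit_set <- function(n = 8, size = 64) {
  cfg <- phantom_config(image_size = size, n_fluid_blobs = 2,
                        n_confounders = 1, noise_sigma = 0,
                        gradient_strength = 0, seed = 11)
  lapply(seq_len(n), function(i) generate_slice(cfg, seed = 100 + i))
}
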