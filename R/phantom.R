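# Synthetic phantom generator.
#
# Emulates the statistical structure of intensity-normalized T2-weighted
# fetal-MRI slices for desk-scale training and evaluation: bright fluid-like
# blobs (the positive class) on a darker background, confounder structures
# of near-fluid intensity that must NOT be segmented, an optional linear
# intensity gradient, and additive Gaussian noise.  Blobs are randomly
# rotated ellipses whose boundaries are perturbed by low-order angular
# harmonics, producing the lobed shapes, crevices and soft boundaries that
# make fluid segmentation non-trivial.

with_seed <- function(seed, expr) {
  old <- get0(".Random.seed", globalenv(), inherits = FALSE)
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, globalenv())
    else if (exists(".Random.seed", globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Deterministic stream of derived seeds (patients, slices) from one master.
derive_seeds <- function(seed, n) {
  with_seed(seed, sample.int(2147483646L, n))
}

#' Phantom generator configuration
#'
#' @param image_size Side length in pixels of the square slices (512 matches
#'   the resolution the reference network is designed for; tests use 64).
#' @param n_fluid_blobs Number of fluid regions per slice (mask label 1).
#' @param n_confounders Number of similar-intensity distractor regions per
#'   slice (mask label 0); their intensity is drawn within ±0.05 of the
#'   fluid intensity so that global thresholding cannot separate them.
#' @param fluid_intensity Mean fluid intensity, in `(0.5, 1]`.
#' @param background_intensity Background intensity, in `[0, 0.5)`.
#' @param noise_sigma Standard deviation of additive Gaussian noise.
#' @param gradient_strength Amplitude of a left-to-right linear intensity
#'   gradient, in `[0, 1]` (applied as `strength * (x/S - 1/2)`).
#' @param seed Default master seed used by the generators.
#' @return A list of class `"af_phantom_config"`.
#' @export
phantom_config <- function(image_size = 512L, n_fluid_blobs = 3L,
                           n_confounders = 3L, fluid_intensity = 0.85,
                           background_intensity = 0.2, noise_sigma = 0.03,
                           gradient_strength = 0.15, seed = 1L) {
  if (image_size < 8) stop("image_size must be a positive integer >= 8")
  if (n_fluid_blobs < 1) stop("n_fluid_blobs must be >= 1")
  if (n_confounders < 0) stop("n_confounders must be >= 0")
  if (fluid_intensity <= 0.5 || fluid_intensity > 1)
    stop("fluid_intensity must lie in (0.5, 1]")
  if (background_intensity < 0 || background_intensity >= 0.5)
    stop("background_intensity must lie in [0, 0.5)")
  if (fluid_intensity <= background_intensity)
    stop("fluid_intensity must exceed background_intensity")
  if (noise_sigma < 0) stop("noise_sigma must be >= 0")
  if (gradient_strength < 0 || gradient_strength > 1)
    stop("gradient_strength must lie in [0, 1]")
  structure(list(image_size = as.integer(image_size),
                 n_fluid_blobs = as.integer(n_fluid_blobs),
                 n_confounders = as.integer(n_confounders),
                 fluid_intensity = fluid_intensity,
                 background_intensity = background_intensity,
                 noise_sigma = noise_sigma,
                 gradient_strength = gradient_strength,
                 seed = as.integer(seed)),
            class = "af_phantom_config")
}

# Random lobed ellipse: centre (fractions of S), semi-axes, rotation and
# boundary harmonics r(theta) = 1 + sum_k amp_k * sin(k*theta + phase_k).
sample_blob <- function(size, axis_range = c(0.08, 0.18),
                        centre_range = c(0.25, 0.75)) {
  list(cx = stats::runif(1, centre_range[1], centre_range[2]) * size,
       cy = stats::runif(1, centre_range[1], centre_range[2]) * size,
       a = stats::runif(1, axis_range[1], axis_range[2]) * size,
       b = stats::runif(1, axis_range[1], axis_range[2]) * size,
       rot = stats::runif(1, 0, pi),
       amp = stats::rnorm(4, 0, 0.03),
       phase = stats::runif(4, 0, 2 * pi))
}

#' Rasterize a lobed-ellipse blob
#'
#' Marks every pixel whose elliptical radius lies inside the harmonically
#' perturbed boundary.  Exposed so tests can recompute blob areas
#' independently of the generator.
#'
#' @param blob A blob parameter list (fields `cx, cy, a, b, rot, amp,
#'   phase`), e.g. from a sample's `meta`.
#' @param size Image side length in pixels.
#' @return Logical `size x size` matrix.
#' @export
rasterize_blob <- function(blob, size) {
  y <- matrix(seq_len(size), size, size)        # row coordinate
  x <- matrix(seq_len(size), size, size, byrow = TRUE)
  u <- (x - blob$cx) * cos(blob$rot) + (y - blob$cy) * sin(blob$rot)
  v <- -(x - blob$cx) * sin(blob$rot) + (y - blob$cy) * cos(blob$rot)
  r <- sqrt((u / blob$a)^2 + (v / blob$b)^2)
  theta <- atan2(v, u)
  lim <- 1
  for (k in seq_along(blob$amp))
    lim <- lim + blob$amp[k] * sin((k + 1) * theta + blob$phase[k])
  r <= lim
}

compose_sample <- function(config, fluid_blobs, confounders, noise_seed) {
  S <- config$image_size
  img <- matrix(config$background_intensity, S, S)
  mask <- matrix(0L, S, S)
  fluid_region <- matrix(FALSE, S, S)
  for (bl in fluid_blobs) fluid_region <- fluid_region | rasterize_blob(bl, S)
  for (cf in confounders) {
    inside <- rasterize_blob(cf, S) & !fluid_region
    img[inside] <- cf$intensity
  }
  img[fluid_region] <- config$fluid_intensity
  mask[fluid_region] <- 1L
  if (config$gradient_strength > 0) {
    gx <- matrix((seq_len(S) / S - 0.5) * config$gradient_strength,
                 S, S, byrow = TRUE)
    img <- img + gx
  }
  if (config$noise_sigma > 0)
    img <- img + with_seed(noise_seed,
                           matrix(stats::rnorm(S * S, 0, config$noise_sigma), S, S))
  img <- pmin(pmax(img, 0), 1)
  structure(list(image = img, mask = mask,
                 meta = list(seed = noise_seed, config = config,
                             fluid_blobs = fluid_blobs,
                             confounders = confounders)),
            class = "af_sample")
}

# Draw confounders that avoid the fluid region (rejection with fallback).
sample_confounders <- function(config, fluid_blobs) {
  S <- config$image_size
  fluid_region <- matrix(FALSE, S, S)
  for (bl in fluid_blobs) fluid_region <- fluid_region | rasterize_blob(bl, S)
  out <- list()
  n <- config$n_confounders
  if (n < 1) return(out)
  for (i in seq_len(n)) {
    for (try in 1:25) {
      cf <- sample_blob(S, axis_range = c(0.04, 0.10),
                        centre_range = c(0.1, 0.9))
      cf$intensity <- config$fluid_intensity + stats::runif(1, -0.05, 0.05)
      cf$intensity <- min(max(cf$intensity, 0), 1)
      if (!any(rasterize_blob(cf, S) & fluid_region) || try == 25) break
    }
    out[[i]] <- cf
  }
  out
}

#' Generate a synthetic 2-D slice
#'
#' Produces one image/mask pair: `n_fluid_blobs` bright lobed regions
#' (mask 1), `n_confounders` distractor regions at near-fluid intensity
#' (mask 0), an optional linear gradient and Gaussian noise.  Deterministic
#' given `(config, seed)`.
#'
#' @param config An [phantom_config()].
#' @param seed Seed for this slice; defaults to `config$seed`.
#' @return An `"af_sample"`: list with `image` (matrix in `[0,1]`), `mask`
#'   (binary integer matrix) and `meta` (seed plus the exact blob
#'   parameters, so regions can be re-rasterized independently).
#' @export
generate_slice <- function(config, seed = config$seed) {
  stopifnot(inherits(config, "af_phantom_config"))
  with_seed(seed, {
    fluid <- lapply(seq_len(config$n_fluid_blobs),
                    function(i) sample_blob(config$image_size))
    conf <- sample_confounders(config, fluid)
    compose_sample(config, fluid, conf, noise_seed = seed + 1L)
  })
}

# Scale a volume-level blob to slice z: spherical cap profile around its
# z-centre plus a linear in-plane drift, so adjacent masks overlap.
blob_at_slice <- function(vb, z) {
  t <- (z - vb$z0) / vb$half_span
  if (abs(t) >= 1) return(NULL)
  sc <- sqrt(1 - t^2)
  if (sc * min(vb$a, vb$b) < 1) return(NULL)   # sub-pixel: drop
  bl <- vb
  bl$a <- vb$a * sc
  bl$b <- vb$b * sc
  bl$cx <- vb$cx + vb$dx * (z - vb$z0)
  bl$cy <- vb$cy + vb$dy * (z - vb$z0)
  bl
}

#' Generate a synthetic 3-D volume
#'
#' Stacks slices whose blob parameters vary smoothly along the slice axis:
#' each fluid blob (and confounder) is a 3-D lobed ellipsoid with a
#' spherical-cap size profile and a linear in-plane drift, so masks of
#' adjacent slices overlap as in real anatomy.
#'
#' @param config An [phantom_config()].
#' @param n_slices Number of slices (clinically 50-120 per patient).
#' @param seed Master seed for the volume; defaults to `config$seed`.
#' @param voxel_spacing `(dz, dy, dx)` in millimetres.
#' @return An `"af_volume"`: list with `slices` (list of `"af_sample"`) and
#'   `voxel_spacing`.
#' @export
generate_volume <- function(config, n_slices, seed = config$seed,
                            voxel_spacing = c(3.0, 0.8, 0.8)) {
  stopifnot(inherits(config, "af_phantom_config"))
  n_slices <- as.integer(n_slices)
  if (is.na(n_slices) || n_slices < 1L) stop("n_slices must be >= 1")
  S <- config$image_size
  vol_pars <- with_seed(seed, {
    fl <- lapply(seq_len(config$n_fluid_blobs), function(i) {
      vb <- sample_blob(S)
      vb$z0 <- stats::runif(1, 0.25, 0.75) * n_slices
      vb$half_span <- stats::runif(1, 0.35, 0.6) * n_slices + 1
      vb$dx <- stats::runif(1, -0.5, 0.5) * S / max(n_slices, 2) * 0.2
      vb$dy <- stats::runif(1, -0.5, 0.5) * S / max(n_slices, 2) * 0.2
      vb
    })
    cf <- lapply(seq_len(config$n_confounders), function(i) {
      vb <- sample_blob(S, axis_range = c(0.04, 0.10), centre_range = c(0.1, 0.9))
      vb$intensity <- min(max(config$fluid_intensity +
                                stats::runif(1, -0.05, 0.05), 0), 1)
      vb$z0 <- stats::runif(1, 0.2, 0.8) * n_slices
      vb$half_span <- stats::runif(1, 0.3, 0.5) * n_slices + 1
      vb$dx <- 0; vb$dy <- 0
      vb
    })
    list(fluid = fl, conf = cf)
  })
  slice_seeds <- derive_seeds(seed, n_slices)
  slices <- lapply(seq_len(n_slices), function(z) {
    fl <- Filter(Negate(is.null), lapply(vol_pars$fluid, blob_at_slice, z = z))
    cf <- Filter(Negate(is.null), lapply(vol_pars$conf, blob_at_slice, z = z))
    compose_sample(config, fl, cf, noise_seed = slice_seeds[z])
  })
  structure(list(slices = slices, voxel_spacing = voxel_spacing,
                 meta = list(seed = seed, n_slices = n_slices)),
            class = "af_volume")
}

#' Generate a synthetic multi-patient dataset
#'
#' @param config An [phantom_config()].
#' @param n_patients Number of independent volumes.
#' @param n_slices_range Inclusive range the per-patient slice count is
#'   drawn from (50-120 emulates clinical sequences; tests use small
#'   ranges).
#' @param seed Master seed; per-patient seeds are derived from it.
#' @param voxel_spacing Passed to [generate_volume()].
#' @return List of `"af_volume"` objects.
#' @export
generate_dataset <- function(config, n_patients,
                             n_slices_range = c(50L, 120L),
                             seed = config$seed,
                             voxel_spacing = c(3.0, 0.8, 0.8)) {
  stopifnot(inherits(config, "af_phantom_config"))
  if (n_patients < 1) stop("n_patients must be >= 1")
  pat_seeds <- derive_seeds(seed, n_patients)
  counts <- with_seed(seed + 1L,
                      sample(seq(n_slices_range[1], n_slices_range[2]),
                             n_patients, replace = TRUE))
  lapply(seq_len(n_patients), function(i)
    generate_volume(config, counts[i], seed = pat_seeds[i],
                    voxel_spacing = voxel_spacing))
}

#' @export
print.af_sample <- function(x, ...) {
  cat("phantom slice ", nrow(x$image), "x", ncol(x$image),
      ", fluid pixels: ", sum(x$mask), " (",
      sprintf("%.1f", 100 * mean(x$mask)), "%)\n", sep = "")
  invisible(x)
}

#' @export
print.af_volume <- function(x, ...) {
  d <- dim(x$slices[[1]]$image)
  cat("phantom volume: ", length(x$slices), " slices of ", d[1], "x", d[2],
      ", spacing (", paste(x$voxel_spacing, collapse = ", "), ") mm\n",
      sep = "")
  invisible(x)
}
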