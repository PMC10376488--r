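# File I/O: PNG slice/mask pairs, NIfTI volumes with voxel spacing, JSON
# metric reports, and the four-colour confusion overlay renderer.

#' Overlay colour specification
#'
#' Pixel-wise confusion colouring for prediction-vs-truth comparisons:
#' light blue for true positives, dark blue for false positives, white for
#' false negatives and grey for true negatives.
#'
#' @param tp_color,fp_color,fn_color,tn_color RGB triplets in 0-255.
#' @return List of class `"af_overlay_spec"`.
#' @export
overlay_spec <- function(tp_color = c(102, 178, 255),
                         fp_color = c(0, 0, 139),
                         fn_color = c(255, 255, 255),
                         tn_color = c(128, 128, 128)) {
  cols <- list(tp = tp_color, fp = fp_color, fn = fn_color, tn = tn_color)
  for (nm in names(cols)) {
    if (length(cols[[nm]]) != 3 || any(cols[[nm]] < 0) || any(cols[[nm]] > 255))
      stop("colours must be RGB triplets in 0..255")
  }
  if (anyDuplicated(vapply(cols, paste, character(1), collapse = ",")))
    stop("the four overlay colours must be pairwise distinct")
  structure(cols, class = "af_overlay_spec")
}

#' Render a confusion overlay
#'
#' Colours every pixel by its confusion class; the per-colour pixel counts
#' equal [confusion_counts()] exactly.
#'
#' @param pred,truth Binary masks of identical shape.
#' @param spec An [overlay_spec()].
#' @return An `H x W x 3` RGB array in `[0, 1]`.
#' @export
render_overlay <- function(pred, truth, spec = overlay_spec()) {
  if (!identical(dim(pred), dim(truth)))
    stop("pred and truth must have identical shape")
  check_binary(pred, "pred"); check_binary(truth, "truth")
  p <- pred == 1; t <- truth == 1
  out <- array(0, dim = c(dim(pred), 3))
  paint <- function(sel, rgb) {
    for (k in 1:3) {
      ch <- out[, , k]
      ch[sel] <- rgb[k] / 255
      out[, , k] <<- ch
    }
  }
  paint(p & t, spec$tp)
  paint(p & !t, spec$fp)
  paint(!p & t, spec$fn)
  paint(!p & !t, spec$tn)
  out
}

#' Write a phantom sample as a PNG pair
#'
#' The image is written as 8-bit grayscale, the mask as `{0, 255}`.
#'
#' @param sample An `"af_sample"`.
#' @param dir Output directory (created if needed).
#' @param prefix File name prefix; writes `<prefix>_image.png` and
#'   `<prefix>_mask.png`.
#' @return Invisibly, the two paths.
#' @export
write_sample_png <- function(sample, dir, prefix = "slice") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  pi <- file.path(dir, paste0(prefix, "_image.png"))
  pm <- file.path(dir, paste0(prefix, "_mask.png"))
  png::writePNG(sample$image, pi)
  png::writePNG(sample$mask * 1.0, pm)
  invisible(c(image = pi, mask = pm))
}

#' Read a PNG image / mask pair
#'
#' @param image_path,mask_path PNG files; `mask_path` optional.
#' @return An `"af_sample"` (mask read back to `{0, 1}`, `NULL` if absent).
#' @export
read_sample_png <- function(image_path, mask_path = NULL) {
  img <- png::readPNG(image_path)
  if (length(dim(img)) == 3) img <- img[, , 1]
  msk <- NULL
  if (!is.null(mask_path)) {
    msk <- png::readPNG(mask_path)
    if (length(dim(msk)) == 3) msk <- msk[, , 1]
    msk <- matrix(as.integer(msk >= 0.5), nrow(msk), ncol(msk))
  }
  structure(list(image = img, mask = msk,
                 meta = list(source = image_path)),
            class = "af_sample")
}

volume_to_array <- function(volume, what = c("image", "mask")) {
  what <- match.arg(what)
  n <- length(volume$slices)
  d <- dim(volume$slices[[1]]$image)
  arr <- array(0, dim = c(d[1], d[2], n))
  for (i in seq_len(n)) arr[, , i] <- volume$slices[[i]][[what]]
  arr
}

#' Write a phantom volume as NIfTI
#'
#' Writes `<stem>.nii.gz` (image) and `<stem>_mask.nii.gz` (binary mask)
#' with the voxel spacing `(dy, dx, dz)` recorded in the header.
#'
#' @param volume An `"af_volume"`.
#' @param stem Output path without extension.
#' @return Invisibly, the two paths.
#' @export
write_volume_nifti <- function(volume, stem) {
  dir.create(dirname(stem), showWarnings = FALSE, recursive = TRUE)
  sp <- volume$voxel_spacing      # (dz, dy, dx)
  pi <- paste0(stem, ".nii.gz")
  pm <- paste0(stem, "_mask.nii.gz")
  img <- RNifti::asNifti(volume_to_array(volume, "image"))
  RNifti::pixdim(img) <- c(sp[2], sp[3], sp[1])
  RNifti::writeNifti(img, pi)
  msk <- RNifti::asNifti(volume_to_array(volume, "mask"))
  RNifti::pixdim(msk) <- c(sp[2], sp[3], sp[1])
  RNifti::writeNifti(msk, pm, datatype = "uint8")
  invisible(c(image = pi, mask = pm))
}

#' Read a volume from NIfTI or a directory of PNG slices
#'
#' @param path A `.nii`/`.nii.gz` file, or a directory containing ordered
#'   `*_image.png` slices (with optional matching `*_mask.png`).
#' @param mask_path Optional NIfTI mask file; defaults to
#'   `<stem>_mask.nii.gz` when it exists.
#' @param spacing `(dz, dy, dx)` in mm; required for PNG directories,
#'   read from the header for NIfTI.
#' @return An `"af_volume"`.
#' @export
read_volume <- function(path, mask_path = NULL, spacing = NULL) {
  if (dir.exists(path)) {
    if (is.null(spacing))
      stop("reading a PNG directory requires explicit voxel spacing")
    imgs <- sort(list.files(path, pattern = "_image\\.png$", full.names = TRUE))
    if (length(imgs) == 0) stop("no *_image.png slices found in ", path)
    slices <- lapply(imgs, function(f) {
      mf <- sub("_image\\.png$", "_mask.png", f)
      read_sample_png(f, if (file.exists(mf)) mf else NULL)
    })
    return(structure(list(slices = slices, voxel_spacing = spacing,
                          meta = list(source = path)),
                     class = "af_volume"))
  }
  if (!file.exists(path)) stop("cannot read ", path)
  nii <- RNifti::readNifti(path)
  arr <- as.array(nii)
  if (length(dim(arr)) != 3) stop("expected a 3-D NIfTI volume")
  pd <- RNifti::pixdim(nii)      # (dy, dx, dz) as written
  sp <- if (!is.null(spacing)) spacing else c(pd[3], pd[1], pd[2])
  if (is.null(mask_path)) {
    cand <- sub("\\.nii(\\.gz)?$", "_mask.nii.gz", path)
    if (file.exists(cand) && cand != path) mask_path <- cand
  }
  msk <- if (!is.null(mask_path)) as.array(RNifti::readNifti(mask_path))
  slices <- lapply(seq_len(dim(arr)[3]), function(i) {
    structure(list(image = arr[, , i],
                   mask = if (!is.null(msk))
                     matrix(as.integer(msk[, , i] >= 0.5), dim(arr)[1]),
                   meta = list(source = path, slice = i)),
              class = "af_sample")
  })
  structure(list(slices = slices, voxel_spacing = sp,
                 meta = list(source = path)),
            class = "af_volume")
}

#' Write a metric report as JSON
#'
#' @param report An `"af_metric_report"`.
#' @param path Output JSON file.
#' @return Invisibly, `path`.
#' @export
write_metric_report <- function(report, path) {
  obj <- list(aggregate = list(miou = report$miou, miou_sd = report$miou_sd,
                               dice = report$dice,
                               precision = report$precision,
                               recall = report$recall,
                               dice_loss = report$dice_loss,
                               n_images = report$n_images),
              per_image = report$per_image)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE,
                       dataframe = "rows")
  invisible(path)
}

#' Write a run manifest
#'
#' Every CLI run records its command, configuration, seed and paths so the
#' run directory can be reproduced.
#'
#' @param dir Run directory.
#' @param command Subcommand name.
#' @param args Named list of resolved options.
#' @return Invisibly, the manifest path.
#' @export
write_manifest <- function(dir, command, args) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  man <- list(command = command, args = args,
              timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
              package_version = as.character(utils::packageVersion("afnet")))
  p <- file.path(dir, "manifest.json")
  jsonlite::write_json(man, p, auto_unbox = TRUE, null = "null")
  invisible(p)
}
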