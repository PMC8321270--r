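# Volume containers and intensity preprocessing.
#
# Axis convention: arrays are kept in stored order (x, y, z), first index
# fastest, exactly as read from disk. No reorientation to an anatomical frame
# is performed anywhere in the package.

#' Create a volume
#'
#' A `volume` is a 3D intensity array together with its physical voxel
#' spacing in millimetres and an optional physical origin.
#'
#' @param data 3D numeric array of intensities, stored (x, y, z).
#' @param spacing numeric length-3, voxel spacing in mm per axis; all > 0.
#' @param origin optional numeric length-3 physical offset in mm.
#' @return An object of class `volume`.
#' @seealso [mask_volume()], [read_volume()], [write_volume()]
#' @export
volume <- function(data, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  if (length(dim(data)) != 3L)
    stop("volume data must have exactly 3 axes, got ", length(dim(data)))
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("spacing must be 3 positive numbers (mm)")
  structure(list(data = data, spacing = spacing, origin = as.numeric(origin)),
            class = "volume")
}

#' Create a mask volume
#'
#' A `mask_volume` holds a binary or probabilistic (soft) label array on the
#' same grid as a paired [volume()]. All values must lie in \[0, 1\].
#'
#' @param data 3D numeric array with values in \[0, 1\].
#' @param spacing numeric length-3 voxel spacing in mm.
#' @param is_binary logical; if `NULL` (default), detected from the data.
#' @return An object of class `mask_volume`.
#' @export
mask_volume <- function(data, spacing = c(1, 1, 1), is_binary = NULL) {
  if (length(dim(data)) != 3L)
    stop("mask data must have exactly 3 axes, got ", length(dim(data)))
  rng <- range(data)
  if (rng[1] < 0 || rng[2] > 1)
    stop("mask values must lie in [0, 1]; observed range [",
         signif(rng[1], 4), ", ", signif(rng[2], 4), "]")
  if (is.null(is_binary)) is_binary <- all(data == 0 | data == 1)
  structure(list(data = data, spacing = as.numeric(spacing),
                 is_binary = isTRUE(is_binary)),
            class = "mask_volume")
}

#' @export
print.volume <- function(x, ...) {
  cat("<volume> ", paste(dim(x$data), collapse = " x "),
      " voxels, spacing ", paste(signif(x$spacing, 4), collapse = " x "),
      " mm, intensity range [", signif(min(x$data), 4), ", ",
      signif(max(x$data), 4), "]\n", sep = "")
  invisible(x)
}

#' @export
print.mask_volume <- function(x, ...) {
  cat("<mask_volume> ", paste(dim(x$data), collapse = " x "),
      " voxels, ", if (x$is_binary) "binary" else "soft",
      ", foreground fraction ", signif(mean(x$data > 0), 3), "\n", sep = "")
  invisible(x)
}

vol_data <- function(x) {
  if (inherits(x, c("volume", "mask_volume"))) x$data
  else if (is.array(x) && length(dim(x)) == 3L) x
  else stop("expected a volume, mask_volume or 3D array")
}

supported_ext <- function(path) {
  if (grepl("\\.nii(\\.gz)?$", path, ignore.case = TRUE)) "nifti"
  else if (grepl("\\.mhd$", path, ignore.case = TRUE)) "mhd"
  else NA_character_
}

#' Read a volume from NIfTI or MetaImage
#'
#' Supported formats are NIfTI (`.nii`, `.nii.gz`) and MetaImage
#' (`.mhd` + `.raw`). The array is returned in stored (x, y, z) order with
#' the voxel spacing taken from the header.
#'
#' @param path path to a `.nii`, `.nii.gz` or `.mhd` file.
#' @param as_mask logical; if `TRUE` return a [mask_volume()] (values are
#'   validated to lie in \[0, 1\]).
#' @return A [volume()] (or [mask_volume()]).
#' @export
read_volume <- function(path, as_mask = FALSE) {
  if (!file.exists(path)) stop("file does not exist: ", path)
  fmt <- supported_ext(path)
  if (is.na(fmt))
    stop("unsupported volume format for ", path,
         " (expected .nii, .nii.gz or .mhd)")
  if (fmt == "nifti") {
    img <- tryCatch(RNifti::readNifti(path),
                    error = function(e) stop("failed to read NIfTI file ",
                                             path, ": ", conditionMessage(e)))
    data <- unclass(as.array(img))
    attributes(data) <- list(dim = dim(data))
    spacing <- RNifti::pixdim(img)
    origin <- c(0, 0, 0)
  } else {
    m <- read_mhd(path)
    data <- m$data
    spacing <- m$spacing
    origin <- m$origin
  }
  if (length(dim(data)) == 4L && dim(data)[4] == 1L) {
    data <- array(data, dim(data)[1:3])
  }
  if (length(dim(data)) != 3L)
    stop("expected a 3D volume in ", path, " but payload has ",
         length(dim(data)), " axes")
  spacing <- as.numeric(spacing)[seq_len(3)]
  if (as_mask) mask_volume(data, spacing) else volume(data, spacing, origin)
}

#' Write a volume or mask to NIfTI or MetaImage
#'
#' Binary masks are stored as unsigned 8-bit integers (lossless); everything
#' else as 32-bit float. Header spacing is set from the object's spacing.
#'
#' @param x a [volume()] or [mask_volume()].
#' @param path output path ending in `.nii`, `.nii.gz` or `.mhd`.
#' @return `path`, invisibly.
#' @export
write_volume <- function(x, path) {
  if (!inherits(x, c("volume", "mask_volume")))
    stop("x must be a volume or mask_volume")
  if (!dir.exists(dirname(path)))
    stop("parent directory does not exist: ", dirname(path))
  fmt <- supported_ext(path)
  if (is.na(fmt))
    stop("unsupported volume format for ", path)
  binary <- inherits(x, "mask_volume") && x$is_binary
  if (fmt == "nifti") {
    img <- RNifti::asNifti(x$data)
    RNifti::pixdim(img) <- x$spacing
    RNifti::writeNifti(img, path, datatype = if (binary) "uint8" else "float")
  } else {
    write_mhd(x$data, path, spacing = x$spacing,
              origin = if (is.null(x$origin)) c(0, 0, 0) else x$origin,
              type = if (binary) "MET_UCHAR" else "MET_FLOAT")
  }
  invisible(path)
}

#' Clip and rescale CT intensities
#'
#' Clips intensities to the window \[`lo`, `hi`\] in Hounsfield units and
#' rescales linearly to \[0, 1\]: `(clip(x, lo, hi) - lo) / (hi - lo)`. The
#' default window (-1000, 300) spans air to soft tissue/calcification, the
#' standard preprocessing for lung CT.
#'
#' @param x a [volume()] or 3D array.
#' @param lo,hi window bounds in HU; `hi > lo`.
#' @return A [volume()] with values in \[0, 1\].
#' @examples
#' v <- volume(array(c(-1500, -350, 300, 0), c(1, 2, 2)))
#' range(clip_and_scale_ct(v)$data)
#' @export
clip_and_scale_ct <- function(x, lo = -1000, hi = 300) {
  if (hi <= lo) stop("hi must be greater than lo (got lo=", lo, ", hi=", hi, ")")
  d <- vol_data(x)
  out <- (pmin(pmax(d, lo), hi) - lo) / (hi - lo)
  sp <- if (inherits(x, "volume")) x$spacing else c(1, 1, 1)
  volume(out, sp, if (inherits(x, "volume")) x$origin else c(0, 0, 0))
}

#' Rescale intensities by per-volume min-max
#'
#' For modalities without a calibrated intensity scale (e.g. T1 MRI) the
#' volume is rescaled to \[0, 1\] by its own minimum and maximum.
#'
#' @param x a [volume()] or 3D array.
#' @return A [volume()] with values in \[0, 1\].
#' @export
minmax_scale <- function(x) {
  d <- vol_data(x)
  rng <- range(d)
  out <- if (rng[2] > rng[1]) (d - rng[1]) / (rng[2] - rng[1]) else d * 0
  sp <- if (inherits(x, "volume")) x$spacing else c(1, 1, 1)
  volume(out, sp, if (inherits(x, "volume")) x$origin else c(0, 0, 0))
}

#' Zero a volume outside a region of interest
#'
#' Sets intensities outside the (binary) ROI to 0, the post-scaling
#' background value; voxels inside the ROI are unchanged. Used e.g. to
#' restrict chest CT to the lung mask before segmentation.
#'
#' @param x a [volume()].
#' @param roi a binary [mask_volume()] on the same grid.
#' @return A [volume()].
#' @export
apply_roi_mask <- function(x, roi) {
  d <- vol_data(x)
  r <- vol_data(roi)
  if (!identical(dim(d), dim(r)))
    stop("volume and ROI grids differ: ", paste(dim(d), collapse = "x"),
         " vs ", paste(dim(r), collapse = "x"))
  out <- d * (r > 0)
  sp <- if (inherits(x, "volume")) x$spacing else c(1, 1, 1)
  volume(out, sp, if (inherits(x, "volume")) x$origin else c(0, 0, 0))
}

#' Average multiple annotations into a mean mask
#'
#' Voxel-wise arithmetic mean of several raters' masks (e.g. the four
#' reference annotations of a public nodule dataset). The result is a soft
#' mask unless all inputs are binary and identical.
#'
#' @param masks list of [mask_volume()] objects (or 3D arrays) on one grid.
#' @return A [mask_volume()].
#' @export
mean_annotation <- function(masks) {
  if (!is.list(masks) || length(masks) < 1L)
    stop("masks must be a non-empty list")
  arrs <- lapply(masks, vol_data)
  d0 <- dim(arrs[[1]])
  for (i in seq_along(arrs))
    if (!identical(dim(arrs[[i]]), d0))
      stop("mask ", i, " grid differs: ", paste(dim(arrs[[i]]), collapse = "x"),
           " vs ", paste(d0, collapse = "x"))
  out <- Reduce(`+`, arrs) / length(arrs)
  sp <- if (inherits(masks[[1]], "mask_volume")) masks[[1]]$spacing else c(1, 1, 1)
  all_binary <- all(vapply(arrs, function(a) all(a == 0 | a == 1), logical(1)))
  identical_all <- all(vapply(arrs[-1], function(a) identical(a, arrs[[1]]),
                              logical(1)))
  mask_volume(out, sp, is_binary = all_binary && identical_all)
}
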