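# Training targets and losses.

#' Max-pool a ground-truth mask to the coarse grid
#'
#' The stage-1 training target: a low-resolution cell is positive iff its
#' `kernel^3` voxel block contains at least one foreground voxel. Soft masks
#' (e.g. mean annotations) are binarized at `threshold` first; shapes not
#' divisible by `kernel` are zero-padded, so the output shape is
#' `ceiling(dim/kernel)`.
#'
#' @param mask a [mask_volume()] or 3D array with values in \[0, 1\].
#' @param kernel pooling kernel (the model's coarse factor, 8).
#' @param threshold binarization threshold applied to soft masks.
#' @return 3D binary array of shape `ceiling(dim(mask)/kernel)`.
#' @export
maxpool_gt <- function(mask, kernel = 8L, threshold = 0.5) {
  m <- vol_data(mask)
  if (any(m < 0 | m > 1)) stop("mask values must lie in [0, 1]")
  cpp_block_max(m, as.integer(kernel), threshold)
}

#' Weighted binary cross-entropy
#'
#' Mean over voxels of `-(pos_weight * t * log(p) + (1 - t) * log(1 - p))`.
#' A positive-class weight above 1 counteracts the extreme foreground
#' scarcity of the coarse localization targets. With `pos_weight = 1` this
#' is standard binary cross-entropy. Targets may be soft.
#'
#' @param pred array of predicted probabilities in (0, 1).
#' @param target array of targets in \[0, 1\], same shape.
#' @param pos_weight weight on the positive-class term, >= 1 in practice.
#' @return Scalar loss.
#' @export
weighted_cross_entropy <- function(pred, target, pos_weight = 1) {
  p <- vol_data3(pred); t <- vol_data3(target)
  if (!identical(dim(p), dim(t)) && length(p) != length(t))
    stop("pred and target shapes differ")
  p <- pmin(pmax(p, 1e-7), 1 - 1e-7)
  mean(-pos_weight * t * log(p) - (1 - t) * log(1 - p))
}

#' Soft Dice loss
#'
#' `1 - (2 * sum(p * t) + eps) / (sum(p) + sum(t) + eps)`, summed over all
#' voxels. The smoothing term `eps` makes empty ground truth well-behaved
#' (loss 0 when prediction and target are both empty).
#'
#' @param pred array of predicted probabilities.
#' @param target array of targets in \[0, 1\], same shape.
#' @param eps smoothing constant.
#' @return Scalar loss in \[0, 1\] (up to the eps effect).
#' @export
dice_loss <- function(pred, target, eps = 1) {
  p <- vol_data3(pred); t <- vol_data3(target)
  if (!identical(dim(p), dim(t)) && length(p) != length(t))
    stop("pred and target shapes differ")
  1 - (2 * sum(p * t) + eps) / (sum(p) + sum(t) + eps)
}

vol_data3 <- function(x) {
  if (inherits(x, c("volume", "mask_volume"))) x$data else x
}
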