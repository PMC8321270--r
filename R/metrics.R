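# Object-wise evaluation: per-object Dice (so large lesions cannot
# overshadow small ones) and FROC analysis with average recall over a grid
# of false-positive operating points.

#' Confidence score of a predicted component
#'
#' Detections are ranked for FROC by the maximum (default) or mean predicted
#' probability over the component's voxels.
#'
#' @param prob 3D probability array.
#' @param component a `component_set` (with `id`) or an integer vector of
#'   linear voxel indices.
#' @param id component label when `component` is a `component_set`.
#' @param rule `"max"` or `"mean"`.
#' @return Scalar score in \[0, 1\].
#' @export
component_score <- function(prob, component, id = NULL,
                            rule = c("max", "mean")) {
  rule <- match.arg(rule)
  p <- vol_data3(prob)
  vox <- if (inherits(component, "component_set")) {
    if (is.null(id)) stop("pass the component label `id`")
    which(component$labels == id)
  } else as.integer(component)
  if (length(vox) == 0) stop("empty component")
  if (rule == "max") max(p[vox]) else mean(p[vox])
}

#' Match predicted components to ground-truth objects
#'
#' A ground-truth object is hit by a predicted component iff their voxel
#' overlap is at least 1 voxel (and, optionally, at least `min_overlap_frac`
#' of the object's volume). A predicted component overlapping no object is a
#' false positive. One component may hit several objects and vice versa.
#'
#' @param pred a `component_set` of the predicted mask.
#' @param gt a `component_set` of the ground-truth mask, same grid.
#' @param min_overlap_frac minimum overlap as a fraction of the ground-truth
#'   object's volume (0 = any single voxel).
#' @return `list(pairs = data.frame(pred, gt, voxels), gt_hit = logical,
#'   pred_fp = logical)`.
#' @export
match_objects <- function(pred, gt, min_overlap_frac = 0) {
  stopifnot(inherits(pred, "component_set"), inherits(gt, "component_set"))
  if (!identical(dim(pred$labels), dim(gt$labels)))
    stop("prediction and ground-truth grids differ")
  both <- pred$labels > 0L & gt$labels > 0L
  pairs <- data.frame(pred = integer(0), gt = integer(0), voxels = integer(0))
  if (any(both)) {
    tab <- table(pred = pred$labels[both], gt = gt$labels[both])
    df <- as.data.frame(tab, stringsAsFactors = FALSE)
    df <- df[df$Freq > 0, ]
    pairs <- data.frame(pred = as.integer(df$pred), gt = as.integer(df$gt),
                        voxels = as.integer(df$Freq))
    if (min_overlap_frac > 0) {
      keep <- pairs$voxels >= min_overlap_frac * gt$sizes[pairs$gt]
      pairs <- pairs[keep, , drop = FALSE]
    }
  }
  gt_hit <- seq_len(gt$n_components) %in% pairs$gt
  pred_fp <- !(seq_len(pred$n_components) %in% pairs$pred)
  list(pairs = pairs, gt_hit = gt_hit, pred_fp = pred_fp)
}

#' Average Dice score per ground-truth object
#'
#' For each ground-truth object the Dice overlap is computed against the
#' predicted mask restricted to the object's bounding box dilated by
#' `context_margin` voxels, so false positives elsewhere in the volume do
#' not depress the score (they are accounted for by FROC instead); voxels
#' of *other* ground-truth objects falling inside the context box are
#' likewise excluded, so neighbouring lesions score independently. Objects
#' missed entirely score 0; the unweighted mean over objects is returned.
#'
#' @param pred_binary binary predicted mask ([mask_volume()] or array).
#' @param gt a `component_set` of the ground-truth objects.
#' @param context_margin dilation of the object's box, in voxels.
#' @return `list(mean = scalar, per_object = numeric)`; `mean` is `NA` with
#'   a warning when there are no ground-truth objects.
#' @export
object_dice <- function(pred_binary, gt, context_margin = 8L) {
  stopifnot(inherits(gt, "component_set"))
  p <- vol_data3(pred_binary) > 0
  dim(p) <- dim(vol_data3(pred_binary))
  if (!identical(dim(p), dim(gt$labels)))
    stop("prediction and ground-truth grids differ")
  if (gt$n_components == 0) {
    warning("no ground-truth objects; object Dice undefined")
    return(list(mean = NA_real_, per_object = numeric(0)))
  }
  shp <- dim(gt$labels)
  boxes <- boxes_with_margin(gt, margin = context_margin, bounds = shp,
                             space = "fullres")
  per <- numeric(gt$n_components)
  for (l in seq_len(gt$n_components)) {
    b <- boxes[[l]]
    xi <- (b$start[1] + 1):b$stop[1]
    yi <- (b$start[2] + 1):b$stop[2]
    zi <- (b$start[3] + 1):b$stop[3]
    lab <- gt$labels[xi, yi, zi]
    gl <- lab == l
    # voxels of *other* ground-truth objects inside the context box belong
    # to their own score, not to this object's denominator
    pl <- p[xi, yi, zi] & (lab == 0L | gl)
    inter <- sum(pl & gl)
    per[l] <- 2 * inter / (sum(pl) + gt$sizes[l])
    if (is.nan(per[l])) per[l] <- 0
  }
  list(mean = mean(per), per_object = per)
}

#' FROC curve from scored detections
#'
#' Sweeps the detection-score threshold over all distinct scores in
#' descending order; at each threshold the operating point is (total false
#' positives / number of images, hit ground-truth objects / total objects).
#'
#' @param detections data.frame with columns `case_id`, `det_id` (component
#'   label within the case) and `score`.
#' @param matches data.frame with columns `case_id`, `det_id`, `gt_id`
#'   listing which ground-truth objects each detection overlaps.
#' @param n_images number of evaluated images.
#' @param n_gt total number of ground-truth objects (> 0).
#' @return An object of class `froc_curve`: `points` data.frame
#'   (`avg_fp_per_image`, `recall`, `threshold`) sorted by increasing FP
#'   rate, plus `n_images` and `n_gt`.
#' @export
froc_curve <- function(detections, matches, n_images, n_gt) {
  if (n_images < 1) stop("need at least one image")
  if (n_gt < 1) stop("recall is undefined without ground-truth objects")
  if (nrow(detections) == 0) {
    pts <- data.frame(avg_fp_per_image = 0, recall = 0,
                      threshold = NA_real_)
    return(structure(list(points = pts, n_images = n_images, n_gt = n_gt),
                     class = "froc_curve"))
  }
  key <- function(case, det) paste(case, det, sep = "\r")
  det_key <- key(detections$case_id, detections$det_id)
  is_hit_det <- det_key %in% key(matches$case_id, matches$det_id)
  thresholds <- sort(unique(detections$score), decreasing = TRUE)
  pts <- lapply(thresholds, function(th) {
    act <- detections$score >= th
    fp <- sum(act & !is_hit_det)
    act_key <- det_key[act]
    mk <- matches[key(matches$case_id, matches$det_id) %in% act_key, ,
                  drop = FALSE]
    hits <- nrow(unique(mk[, c("case_id", "gt_id")]))
    data.frame(avg_fp_per_image = fp / n_images, recall = hits / n_gt,
               threshold = th)
  })
  pts <- do.call(rbind, pts)
  pts <- pts[order(pts$avg_fp_per_image, pts$recall), ]
  rownames(pts) <- NULL
  structure(list(points = pts, n_images = n_images, n_gt = n_gt),
            class = "froc_curve")
}

#' @export
print.froc_curve <- function(x, ...) {
  cat("<froc_curve> ", nrow(x$points), " operating point(s), ", x$n_gt,
      " ground-truth object(s) over ", x$n_images, " image(s)\n", sep = "")
  cat("  avg recall (FP 0-5, step 0.01): ",
      signif(average_recall(x), 4), "\n", sep = "")
  invisible(x)
}

#' @export
plot.froc_curve <- function(x, ...) {
  graphics::plot(x$points$avg_fp_per_image, x$points$recall, type = "s",
                 xlab = "average false positives per image",
                 ylab = "object-wise recall", ylim = c(0, 1), ...)
  invisible(x)
}

# step-function evaluation: best recall among operating points with
# avg_fp <= f (0 before the first point)
recall_at <- function(curve, f) {
  pts <- curve$points
  vapply(f, function(fi) {
    ok <- pts$avg_fp_per_image <= fi + 1e-12
    if (!any(ok)) 0 else max(pts$recall[ok])
  }, numeric(1))
}

#' Average recall over an FP-rate grid
#'
#' Evaluates the FROC step function on a fixed grid of allowed
#' false-positive rates and averages. The default grid is 0 to 5 FPs per
#' image in steps of 0.01 (501 points).
#'
#' @param curve a [froc_curve()].
#' @param fp_grid numeric grid of FP-per-image operating points.
#' @return Scalar in \[0, 1\].
#' @export
average_recall <- function(curve, fp_grid = seq(0, 5, by = 0.01)) {
  stopifnot(inherits(curve, "froc_curve"))
  mean(recall_at(curve, fp_grid))
}

#' Average recall at the seven classic FP rates
#'
#' The lung-nodule challenge variant: mean recall at 1/8, 1/4, 1/2, 1, 2, 4
#' and 8 FPs per scan.
#'
#' @param curve a [froc_curve()].
#' @return Scalar in \[0, 1\].
#' @export
luna_average_recall <- function(curve) {
  average_recall(curve, fp_grid = c(1/8, 1/4, 1/2, 1, 2, 4, 8))
}

#' Evaluate predictions against ground truth, object-wise
#'
#' Builds the detection table (predicted components with scores) and
#' ground-truth objects for every case, then computes the FROC curve, its
#' average recalls and the mean per-object Dice.
#'
#' @param preds named list of `adaptseg_prediction` objects (or lists with
#'   `prob`, `binary`, `components`, `component_set`), one per case.
#' @param gts named list of ground-truth masks ([mask_volume()] or arrays),
#'   same names/order as `preds`.
#' @param threshold binarization threshold for soft ground truth.
#' @param connectivity component connectivity for ground truth.
#' @param context_margin see [object_dice()].
#' @param min_overlap_frac see [match_objects()].
#' @return `list(metrics = list(avg_recall_0to5, luna_avg_recall,
#'   mean_object_dice, n_gt, n_images, n_fp_at_no_threshold), froc =
#'   froc_curve)`.
#' @export
evaluate_cases <- function(preds, gts, threshold = 0.5, connectivity = 26L,
                           context_margin = 8L, min_overlap_frac = 0) {
  if (length(preds) != length(gts)) stop("preds and gts lengths differ")
  ids <- names(preds)
  if (is.null(ids)) ids <- as.character(seq_along(preds))
  det <- data.frame(case_id = character(0), det_id = integer(0),
                    score = numeric(0))
  mat <- data.frame(case_id = character(0), det_id = integer(0),
                    gt_id = integer(0))
  n_gt <- 0
  dice_all <- numeric(0)
  n_fp <- 0
  for (i in seq_along(preds)) {
    pr <- preds[[i]]
    gm <- vol_data3(gts[[i]])
    gt_cs <- connected_components(gm >= threshold, connectivity)
    n_gt <- n_gt + gt_cs$n_components
    pred_cs <- pr$component_set
    if (is.null(pred_cs))
      pred_cs <- connected_components(vol_data3(pr$binary) > 0, connectivity)
    mm <- match_objects(pred_cs, gt_cs, min_overlap_frac)
    n_fp <- n_fp + sum(mm$pred_fp)
    if (pred_cs$n_components > 0) {
      scores <- if (!is.null(pr$components) && nrow(pr$components) > 0)
        pr$components$score
      else vapply(seq_len(pred_cs$n_components), function(l)
        component_score(vol_data3(pr$prob), pred_cs, l), numeric(1))
      det <- rbind(det, data.frame(case_id = ids[i],
                                   det_id = seq_len(pred_cs$n_components),
                                   score = scores))
      if (nrow(mm$pairs) > 0)
        mat <- rbind(mat, data.frame(case_id = ids[i], det_id = mm$pairs$pred,
                                     gt_id = mm$pairs$gt))
    }
    if (gt_cs$n_components > 0) {
      od <- object_dice(vol_data3(pr$binary), gt_cs, context_margin)
      dice_all <- c(dice_all, od$per_object)
    }
  }
  if (n_gt == 0) stop("no ground-truth objects in any case")
  curve <- froc_curve(det, mat, n_images = length(preds), n_gt = n_gt)
  list(metrics = list(avg_recall_0to5 = average_recall(curve),
                      luna_avg_recall = luna_average_recall(curve),
                      mean_object_dice = mean(dice_all),
                      n_gt = n_gt, n_images = length(preds),
                      n_fp_at_no_threshold = n_fp),
       froc = curve)
}
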