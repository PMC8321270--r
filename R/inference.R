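# Adaptive inference: threshold the coarse probability map, label connected
# components, wrap each in a margined bounding box, decode every box at
# original resolution, and insert the outputs into a zero-filled prediction
# map. Voxels outside all boxes are exactly 0 by construction.

#' Axis-aligned 3D bounding box
#'
#' Half-open, 0-based integer boxes tagged with their coordinate space
#' (`"lowres"` = coarse 1/8-resolution grid, `"fullres"` = voxel grid).
#'
#' @param start,stop integer length-3; `start < stop` componentwise.
#' @param space `"lowres"` or `"fullres"`.
#' @return An object of class `bbox3`.
#' @export
bbox3 <- function(start, stop, space = c("lowres", "fullres")) {
  space <- match.arg(space)
  start <- as.integer(start); stop <- as.integer(stop)
  if (length(start) != 3L || length(stop) != 3L || any(start >= stop))
    stop("bounding box must satisfy start < stop componentwise")
  if (any(start < 0L)) stop("bounding box start must be >= 0")
  structure(list(start = start, stop = stop, space = space), class = "bbox3")
}

#' @export
print.bbox3 <- function(x, ...) {
  cat("<bbox3 ", x$space, "> [", paste(x$start, collapse = ","), ") -- [",
      paste(x$stop, collapse = ","), ")\n", sep = "")
  invisible(x)
}

#' Configure adaptive inference
#'
#' @param threshold probability threshold applied to the coarse map (the
#'   comparison is `>=`).
#' @param margin_lowres bounding-box margin in low-resolution cells; 1 cell
#'   (8 voxels) absorbs coarse-stage boundary errors.
#' @param connectivity 3D neighbourhood for component labelling (6, 18, 26).
#' @param factor coarse downsampling factor (8).
#' @param grid_patch optional integer length-3 tile size in voxels for the
#'   stage-1 forward pass (divisible by 8); `NULL` derives it from
#'   `memory_budget`.
#' @param memory_budget inference memory bound in bytes (default 16 GiB,
#'   a standard workstation RAM constraint).
#' @param overlap how overlapping box predictions combine in the output:
#'   `"last"` (write order, the default) or `"max"`.
#' @return An object of class `inference_config`.
#' @export
inference_config <- function(threshold = 0.5, margin_lowres = 1L,
                             connectivity = 26L, factor = 8L,
                             grid_patch = NULL,
                             memory_budget = 16 * 2^30,
                             overlap = c("last", "max")) {
  overlap <- match.arg(overlap)
  if (threshold <= 0 || threshold >= 1) stop("threshold must lie in (0, 1)")
  if (margin_lowres < 0) stop("margin must be >= 0")
  if (!connectivity %in% c(6L, 18L, 26L))
    stop("connectivity must be 6, 18 or 26")
  if (!is.null(grid_patch)) {
    grid_patch <- as.integer(grid_patch)
    if (length(grid_patch) != 3L || any(grid_patch %% 8L != 0L))
      stop("grid_patch must be 3 integers divisible by 8")
  }
  structure(list(threshold = threshold,
                 margin_lowres = as.integer(margin_lowres),
                 connectivity = as.integer(connectivity),
                 factor = as.integer(factor), grid_patch = grid_patch,
                 memory_budget = memory_budget, overlap = overlap),
            class = "inference_config")
}

#' Binarize a probability map
#'
#' Applies the standard threshold with a `>=` comparison (a cell at exactly
#' the threshold is positive).
#'
#' @param prob numeric array with values in \[0, 1\].
#' @param threshold scalar threshold.
#' @return Logical array of the same shape.
#' @export
binarize <- function(prob, threshold = 0.5) {
  p <- vol_data3(prob)
  out <- p >= threshold
  dim(out) <- dim(p)
  out
}

#' Label connected components of a binary 3D array
#'
#' @param bin logical/0-1 3D array.
#' @param connectivity 6 (faces), 18 (faces+edges) or 26 (full
#'   neighbourhood).
#' @return An object of class `component_set`: `labels` (integer array,
#'   0 = background), `n_components`, `sizes` (voxels per label).
#' @export
connected_components <- function(bin, connectivity = 26L) {
  if (!connectivity %in% c(6L, 18L, 26L))
    stop("connectivity must be 6, 18 or 26")
  b <- vol_data3(bin)
  if (!is.logical(b)) { b <- b > 0; dim(b) <- dim(vol_data3(bin)) }
  lab <- cpp_conn_comp(b, as.integer(connectivity))
  n <- attr(lab, "n_components")
  attr(lab, "n_components") <- NULL
  sizes <- if (n > 0) tabulate(lab[lab > 0L], nbins = n) else integer(0)
  structure(list(labels = lab, n_components = n, sizes = sizes),
            class = "component_set")
}

#' @export
print.component_set <- function(x, ...) {
  cat("<component_set> ", x$n_components, " components, sizes: ",
      paste(utils::head(x$sizes, 10), collapse = ", "),
      if (x$n_components > 10) ", ..." else "", "\n", sep = "")
  invisible(x)
}

#' Margined bounding boxes of labelled components
#'
#' One box per component (ordered by label): the tight box expanded by
#' `margin` cells per side, clamped to the array bounds.
#'
#' @param components a `component_set` (on the low-resolution grid during
#'   adaptive inference).
#' @param margin expansion per side, in cells.
#' @param bounds integer length-3 array shape for clamping; defaults to the
#'   label array's shape.
#' @param space coordinate-space tag for the returned boxes.
#' @return List of [bbox3()].
#' @export
boxes_with_margin <- function(components, margin = 1L,
                              bounds = dim(components$labels),
                              space = "lowres") {
  stopifnot(inherits(components, "component_set"))
  if (margin < 0) stop("margin must be >= 0")
  n <- components$n_components
  if (n == 0) return(list())
  idx <- which(components$labels > 0L)
  coords <- arrayInd(idx, dim(components$labels))
  labs <- components$labels[idx]
  out <- vector("list", n)
  for (l in seq_len(n)) {
    cl <- coords[labs == l, , drop = FALSE]
    lo <- apply(cl, 2, min) - 1L   # to 0-based
    hi <- apply(cl, 2, max)        # exclusive stop = max (1-based) == max0+1
    out[[l]] <- bbox3(pmax(lo - margin, 0L),
                      pmin(hi + margin, as.integer(bounds)), space = space)
  }
  out
}

#' Map a low-resolution box to full resolution
#'
#' Each low-resolution cell covers an 8^3 voxel block, so the box scales by
#' `factor` per axis and is clamped to the full-resolution shape (the
#' ceil-divided coarse grid may overhang the volume).
#'
#' @param box a `"lowres"` [bbox3()].
#' @param factor coarse factor (8).
#' @param full_shape integer length-3 full-resolution shape.
#' @return A `"fullres"` [bbox3()].
#' @export
box_to_fullres <- function(box, factor = 8L, full_shape) {
  stopifnot(inherits(box, "bbox3"))
  if (box$space != "lowres")
    stop("box_to_fullres expects a low-resolution box, got '", box$space, "'")
  bbox3(box$start * factor, pmin(box$stop * factor, as.integer(full_shape)),
        space = "fullres")
}

#' Fraction of the volume covered by boxes
#'
#' `|union of box voxels| / |volume voxels|`; overlaps are counted once.
#' This is the share of the image the detailed stage actually processes
#' (typically a few percent).
#'
#' @param boxes list of `"fullres"` [bbox3()].
#' @param full_shape integer length-3 volume shape.
#' @return Scalar in \[0, 1\].
#' @export
fraction_processed <- function(boxes, full_shape) {
  if (length(boxes) == 0) return(0)
  cover <- array(FALSE, full_shape)
  for (b in boxes) {
    stopifnot(inherits(b, "bbox3"))
    if (b$space != "fullres") stop("fraction_processed expects fullres boxes")
    s <- pmin(b$start, full_shape); e <- pmin(b$stop, full_shape)
    if (any(s >= e)) next
    cover[(s[1] + 1):e[1], (s[2] + 1):e[2], (s[3] + 1):e[3]] <- TRUE
  }
  mean(cover)
}

# choose a lowres tile edge (in cells) under the memory budget
tile_cells_for_budget <- function(net, budget) {
  c2 <- net$channels["x2"]
  # rough bytes per full-res voxel across retained activations and buffers
  bytes_per_vox <- 8 * (2 + 6 * c2 / 8)
  max_vox <- max(budget / bytes_per_vox, 16^3)
  max(2L, as.integer(floor(max_vox^(1 / 3) / 8)))
}

#' Tiled stage-1 forward pass over a large volume
#'
#' Divides the volume into non-overlapping core tiles (on the coarse grid)
#' with an overlapping context halo of the stage-1 receptive field, runs the
#' localization stage per tile, and reassembles the coarse probability map
#' and feature pyramid. With a sufficient halo the result equals a direct
#' full-volume forward pass up to floating-point tolerance, while memory
#' stays within the configured budget.
#'
#' @param x a [volume()] or 3D array.
#' @param params stage-1 parameters, checkpoint or model.
#' @param net the [net_config()] (taken from the model if one is passed).
#' @param cfg an [inference_config()].
#' @return Same structure as [stage1_forward()].
#' @export
grid_predict <- function(x, params, net = NULL, cfg = inference_config()) {
  if (inherits(params, "adaptseg_model") || inherits(params, "adaptseg_ckpt"))
    net <- params$net
  if (is.null(net)) stop("pass the net_config (or a model/checkpoint)")
  params <- resolve_params(params, "s1_")
  d <- vol_data(x)
  check_min_input(dim(d))
  orig <- dim(d)
  dp <- pad_to_multiple(d, 8L)
  G <- dim(dp) %/% 8L
  tile <- if (!is.null(cfg$grid_patch)) cfg$grid_patch %/% 8L
          else rep(tile_cells_for_budget(net, cfg$memory_budget), 3L)
  halo <- net$halo_lowres
  ch <- net$channels
  prob <- array(NA_real_, G)
  f2 <- array(NA_real_, c(4L * G, ch["x2"]))
  f4 <- array(NA_real_, c(2L * G, ch["x4"]))
  f8 <- array(NA_real_, c(G, ch["x8"]))
  starts <- function(n, t) as.integer(seq(0L, n - 1L, by = t))
  for (az in starts(G[3], tile[3])) for (ay in starts(G[2], tile[2]))
    for (ax in starts(G[1], tile[1])) {
      a <- c(ax, ay, az)
      b <- pmin(a + tile, G)
      a0 <- pmax(a - halo, 0L)
      b0 <- pmin(b + halo, G)
      sub <- dp[(8 * a0[1] + 1):(8 * b0[1]), (8 * a0[2] + 1):(8 * b0[2]),
                (8 * a0[3] + 1):(8 * b0[3]), drop = FALSE]
      o <- cpp_stage1_forward(params, sub)
      ca <- a - a0  # core offset within the tile, in cells
      cb <- ca + (b - a)
      prob[(a[1] + 1):b[1], (a[2] + 1):b[2], (a[3] + 1):b[3]] <-
        o$prob[(ca[1] + 1):cb[1], (ca[2] + 1):cb[2], (ca[3] + 1):cb[3]]
      f8[(a[1] + 1):b[1], (a[2] + 1):b[2], (a[3] + 1):b[3], ] <-
        o$f8[(ca[1] + 1):cb[1], (ca[2] + 1):cb[2], (ca[3] + 1):cb[3], ,
             drop = FALSE]
      f4[(2 * a[1] + 1):(2 * b[1]), (2 * a[2] + 1):(2 * b[2]),
         (2 * a[3] + 1):(2 * b[3]), ] <-
        o$f4[(2 * ca[1] + 1):(2 * cb[1]), (2 * ca[2] + 1):(2 * cb[2]),
             (2 * ca[3] + 1):(2 * cb[3]), , drop = FALSE]
      f2[(4 * a[1] + 1):(4 * b[1]), (4 * a[2] + 1):(4 * b[2]),
         (4 * a[3] + 1):(4 * b[3]), ] <-
        o$f2[(4 * ca[1] + 1):(4 * cb[1]), (4 * ca[2] + 1):(4 * cb[2]),
             (4 * ca[3] + 1):(4 * cb[3]), , drop = FALSE]
    }
  list(prob = prob,
       pyramid = structure(list(f2 = f2, f4 = f4, f8 = f8,
                                input_shape = orig, padded_shape = dim(dp)),
                           class = "feature_pyramid"))
}

#' Adaptive two-stage prediction
#'
#' Runs the full coarse-to-fine procedure on a preprocessed volume: tiled
#' stage-1 localization, thresholding at 0.5, connected components, margined
#' boxes, per-box detailed decoding, and insertion into a zero-initialised
#' full-resolution map. The returned components are the connected components
#' of the binarized full-resolution prediction, each scored by
#' [component_score()] for FROC analysis.
#'
#' @param x a [volume()] or 3D array, preprocessed to \[0, 1\].
#' @param model an `adaptseg_model` (or parameter list with both stages plus
#'   a `net` attribute via checkpoint).
#' @param cfg an [inference_config()].
#' @param stage1_probs optional replacement for the stage-1 coarse
#'   probability map (shape `ceiling(dim/8)`), e.g. an oracle derived from
#'   ground truth; the feature pyramid is still computed by the network.
#' @param verbose message when no boxes are proposed.
#' @return An object of class `adaptseg_prediction`: soft probability map
#'   (`prob`, a [mask_volume()]), `binary` mask, `components` data.frame
#'   (`component_id`, `score`, `voxels`, `start_*`/`stop_*`), the proposed
#'   `boxes` (full-resolution), and `fraction_processed`.
#' @export
adaptive_predict <- function(x, model, cfg = inference_config(),
                             stage1_probs = NULL, verbose = FALSE) {
  net <- if (inherits(model, c("adaptseg_model", "adaptseg_ckpt"))) model$net
         else stop("model must be an adaptseg_model or checkpoint")
  params <- model$params
  if (!any(startsWith(names(params), "s2_")))
    stop("model has no trained detailed stage (stage 2)")
  spacing <- if (inherits(x, "volume")) x$spacing else c(1, 1, 1)
  d <- vol_data(x)
  orig <- dim(d)
  s1 <- grid_predict(d, params, net, cfg)
  prob_lr <- if (is.null(stage1_probs)) s1$prob else {
    if (!identical(dim(stage1_probs), dim(s1$prob)))
      stop("stage1_probs must have the coarse-grid shape ",
           paste(dim(s1$prob), collapse = "x"))
    stage1_probs
  }
  G <- dim(prob_lr)
  comp_lr <- connected_components(binarize(prob_lr, cfg$threshold),
                                  cfg$connectivity)
  boxes_lr <- boxes_with_margin(comp_lr, margin = cfg$margin_lowres,
                                bounds = G)
  dp_shape <- s1$pyramid$padded_shape
  pred <- array(0, dp_shape)
  dpad <- pad_to_multiple(d, 8L)
  for (b in boxes_lr) {
    patch <- stage2_forward(params, s1$pyramid, b,
                            image = if (net$use_image_skip) dpad else NULL)
    xi <- (8 * b$start[1] + 1):(8 * b$stop[1])
    yi <- (8 * b$start[2] + 1):(8 * b$stop[2])
    zi <- (8 * b$start[3] + 1):(8 * b$stop[3])
    if (cfg$overlap == "max") {
      pred[xi, yi, zi] <- pmax(pred[xi, yi, zi], patch)
    } else {
      pred[xi, yi, zi] <- patch
    }
  }
  pred <- pred[seq_len(orig[1]), seq_len(orig[2]), seq_len(orig[3]),
               drop = FALSE]
  # a box proposed entirely inside the padding margin of a non-multiple-of-8
  # volume has no full-resolution extent; drop it
  boxes_lr <- Filter(function(b) all(b$start * cfg$factor < orig), boxes_lr)
  boxes_fr <- lapply(boxes_lr, box_to_fullres, factor = cfg$factor,
                     full_shape = orig)
  if (length(boxes_fr) == 0 && verbose)
    message("no regions proposed; returning an all-zero prediction")
  bin <- binarize(pred, cfg$threshold)
  comp_fr <- connected_components(bin, cfg$connectivity)
  comp_df <- data.frame(component_id = integer(0), score = numeric(0),
                        start_x = integer(0), start_y = integer(0),
                        start_z = integer(0), stop_x = integer(0),
                        stop_y = integer(0), stop_z = integer(0),
                        voxels = integer(0))
  if (comp_fr$n_components > 0) {
    tight <- boxes_with_margin(comp_fr, margin = 0L, bounds = orig,
                               space = "fullres")
    comp_df <- do.call(rbind, lapply(seq_len(comp_fr$n_components),
      function(l) {
        data.frame(component_id = l,
                   score = component_score(pred, comp_fr, l),
                   start_x = tight[[l]]$start[1], start_y = tight[[l]]$start[2],
                   start_z = tight[[l]]$start[3], stop_x = tight[[l]]$stop[1],
                   stop_y = tight[[l]]$stop[2], stop_z = tight[[l]]$stop[3],
                   voxels = comp_fr$sizes[l])
      }))
  }
  structure(list(
    prob = mask_volume(pred, spacing, is_binary = FALSE),
    binary = mask_volume(bin * 1, spacing, is_binary = TRUE),
    components = comp_df,
    component_set = comp_fr,
    boxes_lowres = boxes_lr,
    boxes = boxes_fr,
    fraction_processed = fraction_processed(boxes_fr, orig),
    n_boxes = length(boxes_fr)), class = "adaptseg_prediction")
}

#' @export
print.adaptseg_prediction <- function(x, ...) {
  cat("<adaptseg_prediction> ", paste(dim(x$prob$data), collapse = "x"),
      " voxels, ", x$n_boxes, " proposed box(es), ",
      nrow(x$components), " predicted component(s), fraction processed ",
      signif(x$fraction_processed, 3), "\n", sep = "")
  invisible(x)
}
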