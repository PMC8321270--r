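# The two-stage fully-convolutional architecture.
#
# Stage 1 (localization): the input is average-pooled once (x2 per axis),
# passed through a stem convolution, then two stride-2 convolutions down to
# 1/8 of the input resolution where ResBlocks and a 1x1x1 sigmoid head
# produce the block-wise foreground probability map. Features at the x2, x4
# and x8 scales are retained as a pyramid.
#
# Stage 2 (detailed segmentation): for one low-resolution bounding box, the
# cropped x8 features pass through a convolutional trunk with ResBlocks,
# then are upsampled (nearest neighbour + convolution) through the x4 and x2
# pyramid crops and finally joined with the raw image crop at original
# resolution, ending in a 1x1x1 sigmoid head. All convolutions are 3x3x3,
# zero-padded, followed by batch normalization and ReLU (except the heads).

#' Configure the two-stage network
#'
#' Channel widths are configurable; the defaults keep the localization path
#' deliberately light and the detailed path heavier (most of its parameters
#' sit in the cheap coarse-scale trunk), which is what makes adaptive
#' inference fast on a CPU.
#'
#' @param base_width channels at the x4 scale. The x2 stem uses half of
#'   this (fine-scale features dominate CPU cost) and the x8 trunks of both
#'   stages use `width_factor` times this.
#' @param width_factor channel multiplier per downsampling step.
#' @param n_scales number of feature scales between the x2 input grid and
#'   the x8 coarse grid; fixed at 3 by the x8 output contract.
#' @param resblocks_per_scale ResBlocks in the coarse-scale trunks of both
#'   stages.
#' @param decoder_widths integer length-4: stage-2 channels at the x8, x4,
#'   x2 and full-resolution steps; `NULL` derives them from `base_width`.
#' @param use_image_skip should the raw image crop enter the stage-2 decoder
#'   at original resolution? Without it the decoder cannot resolve detail
#'   beyond the x2 grid.
#' @return An object of class `net_config`. The derived fields `rf_margin`
#'   (decoder receptive-field radius in full-resolution voxels) and
#'   `halo_lowres` (stage-1 receptive-field radius in low-resolution cells,
#'   used as the tiling halo) are attached.
#' @export
net_config <- function(base_width = 16L, width_factor = 2L, n_scales = 3L,
                       resblocks_per_scale = 1L, decoder_widths = NULL,
                       use_image_skip = TRUE) {
  base_width <- as.integer(base_width)
  width_factor <- as.integer(width_factor)
  resblocks_per_scale <- as.integer(resblocks_per_scale)
  if (base_width < 1L || width_factor < 1L)
    stop("base_width and width_factor must be >= 1")
  if (as.integer(n_scales) != 3L)
    stop("n_scales is fixed at 3: x2 input downsampling times two stride-2 ",
         "encoder steps must compose to the x8 output grid")
  if (resblocks_per_scale < 0L) stop("resblocks_per_scale must be >= 0")
  c2 <- max(base_width %/% 2L, 2L)
  c4 <- base_width
  c8 <- base_width * width_factor
  if (is.null(decoder_widths))
    decoder_widths <- c(c8, c4, c2, max(c2 %/% 2L, 2L))
  decoder_widths <- as.integer(decoder_widths)
  if (length(decoder_widths) != 4L || any(decoder_widths < 1L))
    stop("decoder_widths must be 4 integers >= 1")
  # receptive-field radius of the decoder in full-res voxels: one 3^3 conv
  # contributes its scale's stride; ResBlocks add two convs each at x8
  rf_margin <- 8L * (1L + 2L * resblocks_per_scale) + 4L + 2L + 1L
  # stage-1 receptive field in low-res cells (for exact tiled inference):
  # stem + down1 span 2 voxels on the x2 grid, down2 spans 2, each trunk
  # conv spans 4; one cell is 4 x2-voxels
  halo_lowres <- as.integer(ceiling((4L + 8L * resblocks_per_scale) / 4)) + 1L
  structure(list(base_width = base_width, width_factor = width_factor,
                 n_scales = 3L, resblocks_per_scale = resblocks_per_scale,
                 decoder_widths = decoder_widths,
                 use_image_skip = isTRUE(use_image_skip),
                 channels = c(x2 = c2, x4 = c4, x8 = c8),
                 rf_margin = rf_margin, halo_lowres = halo_lowres),
            class = "net_config")
}

conv_weight <- function(cin, cout) {
  matrix(rnorm(27 * cin * cout, sd = sqrt(2 / (27 * cin))), 27 * cin, cout)
}

bn_params <- function(prefix, c, suffix = "") {
  out <- list(rep(1, c), rep(0, c), rep(0, c), rep(1, c))
  names(out) <- paste0(prefix, c("_g", "_b", "_rm", "_rv"), suffix)
  out
}

res_params <- function(prefix, c) {
  p <- list()
  p[[paste0(prefix, "_W1")]] <- conv_weight(c, c)
  p <- c(p, bn_params(prefix, c, "1"))
  p[[paste0(prefix, "_W2")]] <- conv_weight(c, c)
  p <- c(p, bn_params(prefix, c, "2"))
  p
}

#' Initialise network parameters
#'
#' He-normal weight initialisation for convolutions; batch-norm scale 1,
#' shift 0, running statistics (0, 1). Stage-1 and stage-2 parameters share
#' one flat named list (prefixes `s1_` / `s2_`).
#'
#' @param config a [net_config()].
#' @param stages which stages to initialise (subset of `c(1, 2)`).
#' @param seed optional integer seed.
#' @return Named list of parameter matrices/vectors.
#' @export
init_network <- function(config, stages = c(1, 2), seed = NULL) {
  stopifnot(inherits(config, "net_config"))
  if (!is.null(seed)) set.seed(seed)
  ch <- config$channels
  R <- config$resblocks_per_scale
  p <- list()
  if (1 %in% stages) {
    p$s1_stem_W <- conv_weight(1, ch["x2"])
    p <- c(p, bn_params("s1_stem", ch["x2"]))
    p$s1_down1_W <- conv_weight(ch["x2"], ch["x4"])
    p <- c(p, bn_params("s1_down1", ch["x4"]))
    p$s1_down2_W <- conv_weight(ch["x4"], ch["x8"])
    p <- c(p, bn_params("s1_down2", ch["x8"]))
    for (r in seq_len(R) - 1L)
      p <- c(p, res_params(paste0("s1_res", r), ch["x8"]))
    p$s1_head_W <- matrix(rnorm(ch["x8"], sd = sqrt(2 / ch["x8"])), ch["x8"], 1)
    p$s1_head_b <- 0
  }
  if (2 %in% stages) {
    dw <- config$decoder_widths
    p$s2_g8_W <- conv_weight(ch["x8"], dw[1])
    p <- c(p, bn_params("s2_g8", dw[1]))
    for (r in seq_len(R) - 1L)
      p <- c(p, res_params(paste0("s2_res", r), dw[1]))
    p$s2_d4_W <- conv_weight(dw[1] + ch["x4"], dw[2])
    p <- c(p, bn_params("s2_d4", dw[2]))
    p$s2_d2_W <- conv_weight(dw[2] + ch["x2"], dw[3])
    p <- c(p, bn_params("s2_d2", dw[3]))
    p$s2_df_W <- conv_weight(dw[3] + as.integer(config$use_image_skip), dw[4])
    p <- c(p, bn_params("s2_df", dw[4]))
    p$s2_head_W <- matrix(rnorm(dw[4], sd = sqrt(2 / dw[4])), dw[4], 1)
    # foreground is sparse even inside a proposed box; starting the head at
    # a low foreground prior keeps the early Dice denominator small so
    # gradients do not vanish
    p$s2_head_b <- -4
  }
  p
}

#' Count trainable parameters per stage
#'
#' Counts convolution weights, batch-norm scales/shifts and head biases
#' (running statistics are not trainable).
#'
#' @param params parameter list from [init_network()].
#' @return Named numeric vector `c(stage1 = , stage2 = )`.
#' @export
count_params <- function(params) {
  trainable <- !grepl("_rm|_rv", names(params))
  n1 <- sum(vapply(params[trainable & startsWith(names(params), "s1_")],
                   length, numeric(1)))
  n2 <- sum(vapply(params[trainable & startsWith(names(params), "s2_")],
                   length, numeric(1)))
  c(stage1 = n1, stage2 = n2)
}

#' Downsample a volume by 2x2x2 average pooling
#'
#' The fixed x2 input downsampling applied before the first stage. Odd axes
#' are handled by edge replication, so the output shape is `ceiling(dim/2)`.
#'
#' @param x a [volume()] or 3D array.
#' @param factor must be 2 (the model's input downsampling factor).
#' @return 3D array of shape `ceiling(dim(x)/2)`.
#' @export
downsample_input <- function(x, factor = 2L) {
  if (as.integer(factor) != 2L)
    stop("the model downsamples its input by exactly 2 per axis")
  d <- vol_data(x)
  cpp_avgpool2(d)
}

pad_to_multiple <- function(a, k = 8L, mode = c("replicate", "zero")) {
  mode <- match.arg(mode)
  d <- dim(a)
  nd <- as.integer(ceiling(d / k) * k)
  if (all(nd == d)) return(a)
  if (mode == "replicate") {
    a[pmin(seq_len(nd[1]), d[1]), pmin(seq_len(nd[2]), d[2]),
      pmin(seq_len(nd[3]), d[3]), drop = FALSE]
  } else {
    out <- array(0, nd)
    out[seq_len(d[1]), seq_len(d[2]), seq_len(d[3])] <- a
    out
  }
}

check_min_input <- function(d) {
  if (any(d < 16L))
    stop("input spatial dims must be >= 16 per axis (8 per axis after the ",
         "x2 input downsampling); got ", paste(d, collapse = "x"))
}

#' Stage-1 forward pass
#'
#' Runs the localization path on a full volume (evaluation mode): the input
#' is padded by edge replication to a multiple of 8 per axis, downsampled
#' x2, and scored. Returns the low-resolution probability map (shape
#' `ceiling(dim/8)`) and the retained feature pyramid.
#'
#' @param params parameter list (stage-1 entries) or an `adaptseg_model`.
#' @param x a [volume()] or 3D array, already preprocessed to \[0, 1\].
#' @return `list(prob = 3D array in (0,1), pyramid = list(f2, f4, f8,
#'   input_shape, padded_shape))`.
#' @export
stage1_forward <- function(params, x) {
  params <- resolve_params(params, "s1_")
  d <- vol_data(x)
  check_min_input(dim(d))
  orig <- dim(d)
  dp <- pad_to_multiple(d, 8L)
  out <- cpp_stage1_forward(params, dp)
  list(prob = out$prob,
       pyramid = structure(list(f2 = out$f2, f4 = out$f4, f8 = out$f8,
                                input_shape = orig, padded_shape = dim(dp)),
                           class = "feature_pyramid"))
}

crop4 <- function(a, start, stop) {
  # 0-based half-open spatial crop of a 4D (x,y,z,c) array
  a[(start[1] + 1):stop[1], (start[2] + 1):stop[2],
    (start[3] + 1):stop[3], , drop = FALSE]
}

#' Stage-2 forward pass for one low-resolution bounding box
#'
#' Decodes the pyramid features inside `box` to a full-resolution
#' probability patch covering exactly the box's 8x-upsampled extent.
#'
#' @param params parameter list (stage-2 entries) or an `adaptseg_model`.
#' @param pyramid feature pyramid from [stage1_forward()] (or
#'   [grid_predict()]).
#' @param box a low-resolution [bbox3()].
#' @param image the original-resolution image ([volume()] or array) the
#'   pyramid was computed from; required when the network uses the raw image
#'   skip.
#' @return 3D probability array of shape `8 * (box$stop - box$start)`.
#' @export
stage2_forward <- function(params, pyramid, box, image = NULL) {
  use_img <- TRUE
  if (inherits(params, "adaptseg_model")) use_img <- params$net$use_image_skip
  params <- resolve_params(params, "s2_")
  stopifnot(inherits(box, "bbox3"))
  if (box$space != "lowres")
    stop("stage2_forward expects a low-resolution box")
  ext <- box$stop - box$start
  if (any(ext <= 0)) stop("empty bounding box")
  lr_dim <- dim(pyramid$f8)[1:3]
  if (any(box$start < 0) || any(box$stop > lr_dim))
    stop("box exceeds the low-resolution grid ",
         paste(lr_dim, collapse = "x"))
  f8 <- crop4(pyramid$f8, box$start, box$stop)
  f4 <- crop4(pyramid$f4, 2 * box$start, 2 * box$stop)
  f2 <- crop4(pyramid$f2, 4 * box$start, 4 * box$stop)
  img <- array(0, c(1, 1, 1))
  if (use_img) {
    if (is.null(image))
      stop("this network consumes the raw image crop; pass `image`")
    di <- vol_data(image)
    if (!identical(dim(di), as.integer(pyramid$input_shape)) &&
        !identical(dim(di), as.integer(pyramid$padded_shape)))
      stop("image shape does not match the pyramid's input shape")
    dip <- pad_to_multiple(di, 8L)
    img <- dip[(8 * box$start[1] + 1):(8 * box$stop[1]),
               (8 * box$start[2] + 1):(8 * box$stop[2]),
               (8 * box$start[3] + 1):(8 * box$stop[3]), drop = FALSE]
  }
  cpp_stage2_forward(params, f8, f4, f2, img, use_img)
}

resolve_params <- function(params, prefix) {
  if (inherits(params, "adaptseg_model")) params <- params$params
  if (inherits(params, "adaptseg_ckpt")) params <- params$params
  if (!is.list(params) || is.null(names(params)))
    stop("params must be a named parameter list, checkpoint or model")
  if (!any(startsWith(names(params), prefix)))
    stop("parameter list has no '", prefix, "' entries; was this stage ",
         "trained?")
  params
}
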