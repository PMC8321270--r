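# Object-aware patch sampling: with probability p_object the training patch
# is constrained to contain at least one foreground voxel, drawn uniformly
# over all such origins; otherwise uniformly over all valid origins. The
# enumeration of foreground-containing origins uses a 3D summed-area table.

cumsum_axis <- function(a, axis) {
  d <- dim(a)
  if (axis == 1) {
    r <- apply(a, c(2, 3), cumsum)
    array(r, d)
  } else if (axis == 2) {
    r <- apply(a, c(1, 3), cumsum)   # dims (d2, d1, d3)
    aperm(array(r, d[c(2, 1, 3)]), c(2, 1, 3))
  } else {
    r <- apply(a, c(1, 2), cumsum)   # dims (d3, d1, d2)
    aperm(array(r, d[c(3, 1, 2)]), c(2, 3, 1))
  }
}

# number of foreground voxels in every patch window; returns an array over
# 1-based origins of shape (d - ps + 1)
window_counts <- function(mask_bin, ps) {
  d <- dim(mask_bin)
  S <- array(0, d + 1L)
  S[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)] <-
    cumsum_axis(cumsum_axis(cumsum_axis(mask_bin, 1), 2), 3)
  no <- d - ps + 1L
  ix0 <- seq_len(no[1]); iy0 <- seq_len(no[2]); iz0 <- seq_len(no[3])
  ix1 <- ix0 + ps[1]; iy1 <- iy0 + ps[2]; iz1 <- iz0 + ps[3]
  S[ix1, iy1, iz1] - S[ix0, iy1, iz1] - S[ix1, iy0, iz1] - S[ix1, iy1, iz0] +
    S[ix0, iy0, iz1] + S[ix0, iy1, iz0] + S[ix1, iy0, iz0] -
    S[ix0, iy0, iz0]
}

# Precompute a fast sampler closure for one case.
make_patch_sampler <- function(vol, mask, patch_size) {
  d <- dim(vol)
  ps <- as.integer(patch_size)
  if (any(d < ps)) {
    # pad: replicate image edges, zero-extend the mask
    vol <- pad_to_shape(vol, pmax(d, ps), "replicate")
    mask <- pad_to_shape(mask, pmax(d, ps), "zero")
    d <- dim(vol)
  }
  no <- d - ps + 1L
  wc <- window_counts((mask >= 0.5) * 1, ps)
  obj_idx <- which(wc > 0)
  n_total <- prod(no)
  function(p_object) {
    # lesion-free cases fall through to purely random origins
    use_obj <- length(obj_idx) > 0 && runif(1) < p_object
    lin <- if (use_obj) obj_idx[sample.int(length(obj_idx), 1)]
           else sample.int(n_total, 1)
    org <- arrayInd(lin, no) - 1L   # 0-based origin
    img <- vol[(org[1] + 1):(org[1] + ps[1]),
               (org[2] + 1):(org[2] + ps[2]),
               (org[3] + 1):(org[3] + ps[3]), drop = FALSE]
    msk <- mask[(org[1] + 1):(org[1] + ps[1]),
                (org[2] + 1):(org[2] + ps[2]),
                (org[3] + 1):(org[3] + ps[3]), drop = FALSE]
    list(image = img, mask = msk, origin = as.integer(org),
         contains_object = any(msk >= 0.5))
  }
}

pad_to_shape <- function(a, nd, mode = c("replicate", "zero")) {
  mode <- match.arg(mode)
  d <- dim(a)
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

#' Sample a training patch
#'
#' With probability `p_object` the patch is constrained to contain at least
#' one foreground voxel (uniform over all such origins); otherwise the
#' origin is uniform over all valid positions. Volumes smaller than the
#' patch are padded (image by edge replication, mask by zeros). If the mask
#' is empty but `p_object > 0`, sampling falls back to random origins with a
#' warning.
#'
#' @param vol a [volume()] or 3D array.
#' @param mask a [mask_volume()] or 3D array on the same grid.
#' @param patch_size integer length-3 patch shape.
#' @param p_object probability of forcing a foreground-containing patch.
#' @return `list(image, mask, origin, contains_object)`; `origin` is the
#'   0-based voxel origin of the patch.
#' @export
sample_patch <- function(vol, mask, patch_size = c(64, 64, 64),
                         p_object = 0.5) {
  v <- vol_data3(vol); m <- vol_data3(mask)
  if (!identical(dim(v), dim(m))) stop("volume and mask grids differ")
  if (p_object > 0 && !any(m >= 0.5))
    warning("mask has no foreground; sampling randomly despite p_object > 0")
  sampler <- make_patch_sampler(v, m, patch_size)
  sampler(p_object)
}
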