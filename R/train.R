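# Two-phase training protocol: the localization stage is trained first with
# weighted cross-entropy against max-pooled targets; the detailed stage is
# then trained with Dice loss on adaptively assembled patch predictions
# while the first stage's weights stay frozen.

#' Configure training
#'
#' Defaults reproduce the reference protocol: 100 epochs of 100 SGD
#' iterations with Nesterov momentum 0.9, learning rate 1e-2 dropped to
#' 1e-3 at epoch 80, batch size 32, patches of 64^3 voxels, and a 0.5
#' probability that a sampled patch contains a ground-truth object.
#'
#' @param epochs,iters_per_epoch training length.
#' @param lr_initial,lr_reduced,lr_drop_epoch step learning-rate schedule:
#'   `lr_initial` for epochs before `lr_drop_epoch`, `lr_reduced` from
#'   `lr_drop_epoch` on.
#' @param momentum Nesterov momentum coefficient.
#' @param batch_size patches per SGD iteration.
#' @param patch_size integer length-3, divisible by 8 per axis.
#' @param p_object probability that a sampled patch contains an object.
#' @param gt_pool_kernel max-pooling kernel for the stage-1 target (the
#'   coarse factor, 8).
#' @param pos_weight positive-class weight for the stage-1 loss; `NULL`
#'   (default) estimates it from the training set as the negative/positive
#'   cell ratio clamped to \[1, 100\].
#' @param dice_eps smoothing constant of the stage-2 Dice loss.
#' @param bn_momentum batch-norm running-statistics momentum.
#' @param seed integer seed for sampling and initialisation.
#' @return An object of class `train_config`.
#' @export
train_config <- function(epochs = 100L, iters_per_epoch = 100L,
                         lr_initial = 1e-2, lr_reduced = 1e-3,
                         lr_drop_epoch = 80L, momentum = 0.9,
                         batch_size = 32L, patch_size = c(64, 64, 64),
                         p_object = 0.5, gt_pool_kernel = 8L,
                         pos_weight = NULL, dice_eps = 1,
                         bn_momentum = 0.1, seed = 1L) {
  patch_size <- as.integer(patch_size)
  if (p_object < 0 || p_object > 1) stop("p_object must lie in [0, 1]")
  if (lr_drop_epoch < 1L) stop("lr_drop_epoch must be >= 1")
  if (any(patch_size %% 8L != 0L))
    stop("patch_size must be divisible by 8 per axis")
  structure(list(epochs = as.integer(epochs),
                 iters_per_epoch = as.integer(iters_per_epoch),
                 lr_initial = lr_initial, lr_reduced = lr_reduced,
                 lr_drop_epoch = as.integer(lr_drop_epoch),
                 momentum = momentum, batch_size = as.integer(batch_size),
                 patch_size = patch_size, p_object = p_object,
                 gt_pool_kernel = as.integer(gt_pool_kernel),
                 pos_weight = pos_weight, dice_eps = dice_eps,
                 bn_momentum = bn_momentum, seed = as.integer(seed)),
            class = "train_config")
}

lr_at_epoch <- function(cfg, epoch) {
  if (epoch >= cfg$lr_drop_epoch) cfg$lr_reduced else cfg$lr_initial
}

manifest_hash <- function(manifest) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  write.csv(manifest[order(manifest$case_id),
                     c("case_id", "n_lesions", "diameters_mm")],
            tmp, row.names = FALSE)
  unname(tools::md5sum(tmp))
}

load_training_set <- function(manifest) {
  lapply(seq_len(nrow(manifest)), function(i) {
    v <- read_volume(manifest$volume_path[i])
    m <- read_volume(manifest$mask_path[i], as_mask = TRUE)
    if (!identical(dim(v$data), dim(m$data)))
      stop("case ", manifest$case_id[i], ": volume and mask grids differ")
    list(vol = v$data, mask = m$data)
  })
}

# Nesterov SGD: v <- mu v + g;  p <- p - lr (g + mu v)
sgd_update <- function(params, grads, velocity, lr, mu) {
  for (nm in names(grads)) {
    g <- grads[[nm]]
    v <- if (is.null(velocity[[nm]])) g * 0 else velocity[[nm]]
    v <- mu * v + g
    velocity[[nm]] <- v
    params[[nm]] <- params[[nm]] - lr * (g + mu * v)
  }
  list(params = params, velocity = velocity)
}

estimate_pos_weight <- function(cases, kernel) {
  pos <- 0; tot <- 0
  for (cs in cases) {
    t <- maxpool_gt(cs$mask, kernel)
    pos <- pos + sum(t)
    tot <- tot + length(t)
  }
  if (pos == 0) {
    warning("training set has no foreground; pos_weight set to 1")
    return(1)
  }
  min(max((tot - pos) / pos, 1), 100)
}

new_ckpt <- function(stage, params, net, train, manifest, log) {
  structure(list(stage = stage, params = params, net = net, train = train,
                 manifest_hash = manifest_hash(manifest), seed = train$seed,
                 log = log),
            class = "adaptseg_ckpt")
}

#' @export
print.adaptseg_ckpt <- function(x, ...) {
  cat("<adaptseg checkpoint> ", x$stage, ", ",
      nrow(x$log), " epochs, final loss ",
      signif(utils::tail(x$log$mean_loss, 1), 4), "\n", sep = "")
  invisible(x)
}

#' Save / load a checkpoint or model
#'
#' Checkpoints are self-describing: they embed the network and training
#' configurations, the training-manifest hash and the seed.
#'
#' @param x an `adaptseg_ckpt` or `adaptseg_model`.
#' @param path file path.
#' @return `load_checkpoint` returns the restored object.
#' @export
save_checkpoint <- function(x, path) {
  saveRDS(x, path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  if (!file.exists(path)) stop("checkpoint does not exist: ", path)
  readRDS(path)
}

#' Train the localization stage
#'
#' Minimises weighted cross-entropy between the stage-1 probability map and
#' the 8^3 max-pooled ground truth over patch batches, with Nesterov SGD
#' under the step learning-rate schedule of the supplied [train_config()].
#'
#' @param manifest training manifest data.frame (see [read_manifest()]) or
#'   path to a manifest CSV.
#' @param net a [net_config()].
#' @param train a [train_config()].
#' @param verbose print per-epoch progress to stderr.
#' @return An `adaptseg_ckpt` with `stage = "stage1"` and a training log
#'   data.frame (`epoch`, `mean_loss`, `lr`).
#' @export
train_stage1 <- function(manifest, net = net_config(),
                         train = train_config(), verbose = TRUE) {
  if (is.character(manifest)) manifest <- read_manifest(manifest)
  if (nrow(manifest) == 0) stop("empty training manifest")
  set.seed(train$seed)
  cases <- load_training_set(manifest)
  params <- init_network(net, stages = 1)
  pw <- if (is.null(train$pos_weight))
    estimate_pos_weight(cases, train$gt_pool_kernel) else train$pos_weight
  samplers <- lapply(cases, function(cs)
    make_patch_sampler(cs$vol, cs$mask, train$patch_size))
  velocity <- list()
  log <- data.frame(epoch = integer(0), mean_loss = numeric(0),
                    lr = numeric(0))
  for (ep in seq_len(train$epochs)) {
    lr <- lr_at_epoch(train, ep)
    losses <- numeric(train$iters_per_epoch)
    for (it in seq_len(train$iters_per_epoch)) {
      ids <- sample.int(length(cases), train$batch_size, replace = TRUE)
      patches <- lapply(ids, function(i) samplers[[i]](train$p_object))
      xs <- lapply(patches, `[[`, "image")
      ts <- lapply(patches, function(p)
        cpp_block_max(p$mask, train$gt_pool_kernel, 0.5))
      step <- cpp_stage1_batch(params, xs, ts, pw, TRUE, TRUE,
                               train$bn_momentum)
      if (!is.finite(step$loss))
        stop("stage-1 training diverged (non-finite loss) at epoch ", ep,
             ", iteration ", it)
      upd <- sgd_update(params, step$grads, velocity, lr, train$momentum)
      params <- upd$params
      velocity <- upd$velocity
      params[names(step$bn_stats)] <- step$bn_stats
      losses[it] <- step$loss
    }
    log <- rbind(log, data.frame(epoch = ep, mean_loss = mean(losses),
                                 lr = lr))
    if (verbose)
      message(sprintf("[stage1] epoch %d/%d loss %.5f lr %g",
                      ep, train$epochs, mean(losses), lr))
  }
  ck <- new_ckpt("stage1", params, net, train, manifest, log)
  ck$pos_weight <- pw
  ck
}

# Propose stage-2 training boxes for one patch: threshold the (frozen)
# stage-1 prediction, label components, add the 1-cell margin. If nothing is
# proposed but the patch holds ground truth, fall back to the boxes of the
# max-pooled ground truth so the second stage still receives gradient.
propose_patch_boxes <- function(prob_lr, mask_patch, threshold = 0.5,
                                margin = 1L, connectivity = 26L) {
  lr_dim <- dim(prob_lr)
  comp <- connected_components(prob_lr >= threshold, connectivity)
  boxes <- boxes_with_margin(comp, margin = margin, bounds = lr_dim)
  if (length(boxes) == 0 && any(mask_patch >= 0.5)) {
    gt_lr <- maxpool_gt(mask_patch, 8L)
    comp <- connected_components(gt_lr >= 0.5, connectivity)
    boxes <- boxes_with_margin(comp, margin = margin, bounds = lr_dim)
  }
  boxes
}

#' Train the detailed stage with the first stage frozen
#'
#' For every patch the frozen stage-1 network proposes bounding boxes
#' (threshold 0.5, connected components, 1-cell margin); the decoder
#' predicts each box at original resolution and the assembled patch
#' prediction (zeros outside all boxes) is scored with Dice loss against
#' the patch ground truth. Stage-1 weights are bit-identical before and
#' after. Patches whose ground truth the frozen stage misses entirely fall
#' back to ground-truth-derived boxes so the decoder still receives
#' gradient.
#'
#' @param manifest training manifest (data.frame or path); must be the same
#'   set used for stage 1 (checked via the manifest hash, with a warning on
#'   mismatch).
#' @param stage1_ckpt the `adaptseg_ckpt` from [train_stage1()].
#' @param train a [train_config()]; defaults to the stage-1 one.
#' @param verbose print per-epoch progress.
#' @return An `adaptseg_ckpt` with `stage = "stage2"` carrying both stages'
#'   parameters.
#' @export
train_stage2 <- function(manifest, stage1_ckpt, train = NULL,
                         verbose = TRUE) {
  if (is.character(manifest)) manifest <- read_manifest(manifest)
  if (is.character(stage1_ckpt)) stage1_ckpt <- load_checkpoint(stage1_ckpt)
  if (!inherits(stage1_ckpt, "adaptseg_ckpt") ||
      !any(startsWith(names(stage1_ckpt$params), "s1_")))
    stop("stage1_ckpt must be a stage-1 checkpoint")
  net <- stage1_ckpt$net
  if (is.null(train)) train <- stage1_ckpt$train
  if (!identical(manifest_hash(manifest), stage1_ckpt$manifest_hash))
    warning("training manifest differs from the one used for stage 1; ",
            "both stages should be trained on the same set")
  set.seed(train$seed + 1L)
  cases <- load_training_set(manifest)
  s1 <- stage1_ckpt$params[startsWith(names(stage1_ckpt$params), "s1_")]
  params <- init_network(net, stages = 2)
  samplers <- lapply(cases, function(cs)
    make_patch_sampler(cs$vol, cs$mask, train$patch_size))
  velocity <- list()
  log <- data.frame(epoch = integer(0), mean_loss = numeric(0),
                    lr = numeric(0))
  for (ep in seq_len(train$epochs)) {
    lr <- lr_at_epoch(train, ep)
    losses <- numeric(train$iters_per_epoch)
    for (it in seq_len(train$iters_per_epoch)) {
      ids <- sample.int(length(cases), train$batch_size, replace = TRUE)
      patches <- lapply(ids, function(i) samplers[[i]](train$p_object))
      boxlist <- list()
      gts <- vector("list", length(patches))
      s1outs <- cpp_stage1_forward_batch(s1, lapply(patches, `[[`, "image"))
      for (b in seq_along(patches)) {
        pt <- patches[[b]]
        gts[[b]] <- pt$mask
        s1out <- s1outs[[b]]
        boxes <- propose_patch_boxes(s1out$prob, pt$mask)
        for (bx in boxes) {
          boxlist[[length(boxlist) + 1L]] <- list(
            f8 = crop4(s1out$f8, bx$start, bx$stop),
            f4 = crop4(s1out$f4, 2 * bx$start, 2 * bx$stop),
            f2 = crop4(s1out$f2, 4 * bx$start, 4 * bx$stop),
            img = if (net$use_image_skip)
              pt$image[(8 * bx$start[1] + 1):(8 * bx$stop[1]),
                       (8 * bx$start[2] + 1):(8 * bx$stop[2]),
                       (8 * bx$start[3] + 1):(8 * bx$stop[3]),
                       drop = FALSE] else NULL,
            patch = b, off = as.integer(8L * bx$start))
        }
      }
      step <- cpp_stage2_batch(params, boxlist, gts, train$dice_eps, TRUE,
                               train$bn_momentum)
      if (!is.finite(step$loss))
        stop("stage-2 training diverged (non-finite loss) at epoch ", ep,
             ", iteration ", it)
      if (step$n_boxes > 0) {
        upd <- sgd_update(params, step$grads, velocity, lr, train$momentum)
        params <- upd$params
        velocity <- upd$velocity
        params[names(step$bn_stats)] <- step$bn_stats
      }
      losses[it] <- step$loss
    }
    log <- rbind(log, data.frame(epoch = ep, mean_loss = mean(losses),
                                 lr = lr))
    if (verbose)
      message(sprintf("[stage2] epoch %d/%d loss %.5f lr %g",
                      ep, train$epochs, mean(losses), lr))
  }
  new_ckpt("stage2", c(s1, params), net, train, manifest, log)
}

#' Fit the full two-stage segmentation model
#'
#' Convenience front-end running [train_stage1()] and [train_stage2()] on
#' one training manifest and returning a ready-to-predict model object.
#'
#' @param manifest training manifest (data.frame or manifest CSV path).
#' @param net a [net_config()].
#' @param train a [train_config()].
#' @param verbose print progress.
#' @return An object of class `adaptseg_model`; see [predict.adaptseg_model()].
#' @examples
#' \donttest{
#' cfg <- phantom_config(shape = c(48, 48, 48), seed = 7)
#' dir <- file.path(tempdir(), "phantoms")
#' generate_dataset(cfg, 3, dir)
#' fit <- adaptseg_fit(file.path(dir, "manifest.csv"),
#'                     net = net_config(base_width = 4),
#'                     train = train_config(epochs = 1, iters_per_epoch = 2,
#'                                          batch_size = 2,
#'                                          patch_size = c(32, 32, 32)),
#'                     verbose = FALSE)
#' print(fit)
#' }
#' @export
adaptseg_fit <- function(manifest, net = net_config(),
                         train = train_config(), verbose = TRUE) {
  if (is.character(manifest)) manifest <- read_manifest(manifest)
  ck1 <- train_stage1(manifest, net, train, verbose = verbose)
  ck2 <- train_stage2(manifest, ck1, train, verbose = verbose)
  structure(list(params = ck2$params, net = net, train = train,
                 manifest_hash = ck2$manifest_hash, seed = train$seed,
                 pos_weight = ck1$pos_weight,
                 logs = list(stage1 = ck1$log, stage2 = ck2$log)),
            class = "adaptseg_model")
}
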