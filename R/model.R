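# S3 interface of the fitted two-stage model.

#' @export
print.adaptseg_model <- function(x, ...) {
  np <- count_params(x$params)
  cat("Adaptive two-stage 3D segmentation model\n")
  cat("  localization stage: ", format(np["stage1"], big.mark = ","),
      " parameters (x8 coarse grid)\n", sep = "")
  cat("  detailed stage:     ", format(np["stage2"], big.mark = ","),
      " parameters (per-box decoder)\n", sep = "")
  if (!is.null(x$logs$stage1))
    cat("  final stage-1 loss: ",
        signif(utils::tail(x$logs$stage1$mean_loss, 1), 4), "\n", sep = "")
  if (!is.null(x$logs$stage2))
    cat("  final stage-2 loss: ",
        signif(utils::tail(x$logs$stage2$mean_loss, 1), 4), "\n", sep = "")
  invisible(x)
}

#' @export
summary.adaptseg_model <- function(object, ...) {
  print(object)
  cat("network: base width ", object$net$base_width, ", ",
      object$net$resblocks_per_scale, " ResBlock(s) per trunk, decoder ",
      paste(object$net$decoder_widths, collapse = "/"),
      if (object$net$use_image_skip) ", raw-image skip" else "",
      "\n", sep = "")
  cat("training: ", object$train$epochs, " epochs x ",
      object$train$iters_per_epoch, " iterations, batch ",
      object$train$batch_size, ", patch ",
      paste(object$train$patch_size, collapse = "x"),
      ", seed ", object$seed, "\n", sep = "")
  if (!is.null(object$pos_weight))
    cat("stage-1 positive-class weight: ", signif(object$pos_weight, 4),
        "\n", sep = "")
  invisible(object)
}

#' Predict segmentations from a fitted model
#'
#' Thin wrapper around [adaptive_predict()].
#'
#' @param object an `adaptseg_model` from [adaptseg_fit()].
#' @param newdata a [volume()] or 3D array, preprocessed to \[0, 1\].
#' @param cfg an [inference_config()].
#' @param ... passed on to [adaptive_predict()].
#' @return An `adaptseg_prediction`.
#' @export
predict.adaptseg_model <- function(object, newdata, cfg = inference_config(),
                                   ...) {
  adaptive_predict(newdata, object, cfg = cfg, ...)
}
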