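# User-facing modelling surface: blindspot() fits a self-supervised
# denoiser and returns a classed object with the usual accessor methods.

#' Fit a self-supervised blind-spot denoiser
#'
#' Trains the light-weight U-Net on noisy B-scans alone: blind-spot centers
#' and their 7x1 axial strips are hidden by continuous-strip replacement,
#' and the network learns to predict the original center values from the
#' surrounding context. Because the noise is (conditionally) zero-mean and
#' its correlation is covered by the strip, the best achievable prediction
#' is the clean signal.
#'
#' @param x training images: a list of matrices / [bscan()]s /
#'   phantom samples, or a `"phantom_dataset"` (its `train` split is used).
#' @param val validation images; defaults to the dataset's `val` split
#'   when `x` is a `"phantom_dataset"`.
#' @param net a [net_spec()]; the default is the artifact-suppressing
#'   variant without residual and top-level skip connections.
#' @param control a [train_config()].
#' @param verbose print per-epoch progress.
#' @return object of class `"blindspot"` (see [train_model()]).
#' @seealso [predict.blindspot()], [residuals.blindspot()],
#'   [plot.blindspot()]
#' @export
blindspot <- function(x, val = NULL, net = net_spec(),
                      control = train_config(), verbose = FALSE) {
  if (inherits(x, "phantom_dataset")) {
    if (is.null(val)) val <- x$val
    x <- x$train
  }
  if (is.null(val)) stopf("a validation set is required")
  net_sp <- if (inherits(net, "net_spec")) net else stopf("net must be a net_spec")
  model <- build_unet(net_sp)
  train_model(model, x, val, control, verbose = verbose)
}

#' @export
print.blindspot <- function(x, ...) {
  cat("Blind-spot denoiser:", format(x$spec), "\n")
  cat(sprintf("  trained %d epoch(s), best validation %.6f at epoch %d\n",
              nrow(x$history),
              if (nrow(x$history)) min(x$history$val_loss) else NA,
              x$best_epoch))
  invisible(x)
}

#' @export
summary.blindspot <- function(object, ...) {
  h <- object$history
  structure(list(spec = object$spec, config = object$config,
                 n_params = length(params_to_vec(object$model$params)),
                 rf = rf_theoretical(object$spec),
                 history = h, best_epoch = object$best_epoch),
            class = "summary.blindspot")
}

#' @export
print.summary.blindspot <- function(x, ...) {
  cat("Blind-spot denoiser:", format(x$spec), "\n")
  cat(sprintf("  parameters: %d   theoretical receptive field: %dx%d px\n",
              x$n_params, x$rf, x$rf))
  cat(sprintf("  profile: %s (%d epochs x %d steps, batch %d, patch %dx%d, lr %g)\n",
              x$config$profile, x$config$epochs, x$config$steps_per_epoch,
              x$config$batch_size, x$config$patch_size[1],
              x$config$patch_size[2], x$config$initial_lr))
  if (nrow(x$history)) {
    cat(sprintf("  best epoch %d: val %.6f; final lr %.3g\n", x$best_epoch,
                min(x$history$val_loss), tail(x$history$lr, 1)))
  } else cat("  untrained (0 epochs)\n")
  invisible(x)
}

#' Model coefficients (network weights)
#'
#' @param object a `"blindspot"` fit.
#' @param ... unused.
#' @return the flat parameter vector; use `object$model$params` for the
#'   structured weight tree.
#' @export
coef.blindspot <- function(object, ...) params_to_vec(object$model$params)

#' Denoise new images with a fitted model
#'
#' @param object a `"blindspot"` fit.
#' @param newdata a matrix / [bscan()] / phantom sample or a list of them.
#' @param pipeline if `TRUE` (default), run the deployment buffer pipeline
#'   (pseudo-batched split/pad/recombine inference); otherwise single-pass
#'   whole-image inference with replicated edge padding.
#' @param spec a [buffer_spec()] for the pipeline path.
#' @param precision `"single"` or `"half"`.
#' @param black_level subtracted (clipped at 0) after denoising, if > 0.
#' @param ... unused.
#' @return denoised image or list of images.
#' @export
predict.blindspot <- function(object, newdata, pipeline = TRUE,
                              spec = buffer_spec(),
                              precision = c("single", "half"),
                              black_level = NULL, ...) {
  precision <- match.arg(precision)
  single <- !is.list(newdata) || inherits(newdata, "phantom_sample")
  imgs <- as_image_list(newdata)
  m4 <- if (pipeline) export_pseudobatch(object$model, spec$sub_buffer_count)
  out <- lapply(imgs, function(img) {
    y <- if (pipeline) denoise_buffer(img, m4, spec, precision = precision)
         else denoise_whole(img, object$model, pad = spec$pad,
                            precision = precision)
    lvl <- black_level %||% spec$black_level
    if (lvl > 0) y <- subtract_black_level(y, lvl)
    y
  })
  if (single) out[[1]] else out
}

#' Estimated noise component of new images
#'
#' The blind-spot residual `noisy - denoised`, i.e. the model's estimate of
#' the zero-mean noise field.
#'
#' @param object a `"blindspot"` fit.
#' @param newdata image(s) to decompose.
#' @param ... passed to [predict.blindspot()].
#' @return residual image or list of images.
#' @export
residuals.blindspot <- function(object, newdata, ...) {
  imgs <- as_image_list(newdata)
  den <- predict(object, imgs, ...)
  out <- Map(function(a, b) a - b, imgs, den)
  if (!is.list(newdata) || inherits(newdata, "phantom_sample")) out[[1]] else out
}

#' Plot training history
#'
#' Training and validation masked-MSE per epoch (log scale) with the
#' learning-rate schedule.
#'
#' @param x a `"blindspot"` fit.
#' @param ... passed to [matplot()].
#' @export
plot.blindspot <- function(x, ...) {
  h <- x$history
  if (!nrow(h)) stopf("no history to plot")
  matplot(h$epoch, cbind(h$train_loss, h$val_loss), type = "l", lty = 1,
          col = c("grey40", "firebrick"), log = "y", xlab = "epoch",
          ylab = "masked MSE", ...)
  legend("topright", c("train", "validation"), lty = 1,
         col = c("grey40", "firebrick"), bty = "n")
  invisible(x)
}
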