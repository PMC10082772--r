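# Self-supervised training: random patch extraction, flip and intensity-range
# augmentation, structured masking, masked MSE on center pixels, Adam with
# plateau-halving learning rate, best-validation checkpointing.

#' Training configuration
#'
#' The `"paper"` profile is the full training regime (300 epochs of 600
#' steps, batch 128, 200x200 patches, initial learning rate 2e-5). The
#' `"desk"` profile is a scaled-down schedule for CPU-scale experiments
#' (30 epochs of 100 steps, batch 16, 64x64 patches); its learning rate of
#' 2e-3 follows Adam step-budget scaling -- with ~60x fewer update steps
#' than the full-scale profile, the rate is scaled up by about two orders
#' of magnitude so the shortened schedule still reaches convergence (the
#' plateau scheduler becomes active within the 30 epochs).
#'
#' @param profile `"desk"` or `"paper"`.
#' @param ... overrides for any field: `epochs`, `steps_per_epoch`,
#'   `batch_size`, `patch_size` (`c(h, w)`, divisible by 4), `initial_lr`,
#'   `plateau_patience`, `lr_factor`, `lr_floor`, `flip_prob`,
#'   `jitter_sigma`, `jitter_clip`, `mask` (a [mask_config()]), `seed`.
#' @return object of class `"train_config"`.
#' @export
train_config <- function(profile = c("desk", "paper"), ...) {
  profile <- match.arg(profile)
  base <- switch(profile,
    paper = list(epochs = 300L, steps_per_epoch = 600L, batch_size = 128L,
                 patch_size = c(200L, 200L), initial_lr = 2e-5),
    desk = list(epochs = 30L, steps_per_epoch = 100L, batch_size = 16L,
                patch_size = c(64L, 64L), initial_lr = 2e-3))
  cfg <- modifyList(c(base, list(
    plateau_patience = 10L, lr_factor = 0.5, lr_floor = 1e-7,
    flip_prob = 0.5, jitter_sigma = 0.25, jitter_clip = c(-1, 1),
    mask = mask_config(), seed = 1L, profile = profile)), list(...))
  stopifnot(cfg$epochs >= 0, cfg$steps_per_epoch >= 0, cfg$batch_size >= 1,
            cfg$flip_prob >= 0, cfg$flip_prob <= 1,
            cfg$lr_factor > 0, cfg$lr_factor < 1)
  if (any(cfg$patch_size %% 4 != 0))
    stopf("patch_size must be divisible by 4")
  class(cfg) <- "train_config"
  cfg
}

#' Augment a training patch
#'
#' With probability `flip_prob`, the patch is reversed along the lateral
#' axis (reversing the scan direction while preserving A-scan structure).
#' Independently, the nominal `[0, 1]` intensity range is remapped to
#' `[max(0, d_lo), 1 + min(0, d_hi)]` with `d_lo, d_hi ~ N(0, jitter_sigma)`
#' clipped to `jitter_clip`, emulating varying black-level subtraction and
#' dynamic-range scaling; each bound moves only inward, so each stays
#' unchanged with probability 1/2 and the whole image with probability 1/4.
#' Draws with an empty target range are redrawn. Uses the current RNG
#' stream.
#'
#' @param patch numeric matrix in nominal `[0, 1]`.
#' @param config a [train_config()].
#' @return the augmented matrix.
#' @export
augment <- function(patch, config) {
  if (runif(1) < config$flip_prob) patch <- patch[, rev(seq_len(ncol(patch))), drop = FALSE]
  repeat {
    d <- pmin(pmax(rnorm(2, 0, config$jitter_sigma), config$jitter_clip[1]),
              config$jitter_clip[2])
    if (max(0, d[1]) < 1 + min(0, d[2])) break
  }
  remap_range(patch, d[1], d[2])
}

# Linear remap of [0, 1] to [max(0, d_lo), 1 + min(0, d_hi)]: bounds only
# move inward, so a draw pushing a bound outward leaves it unchanged.
remap_range <- function(patch, d_lo, d_hi) {
  b_lo <- max(0, d_lo)
  b_hi <- 1 + min(0, d_hi)
  if (b_lo >= b_hi) stopf("empty target range")
  b_lo + patch * (b_hi - b_lo)
}

#' Masked mean squared error
#'
#' Mean of squared differences over the pixels marked in `loss_mask` (the
#' blind-spot centers); `target` holds the original, pre-masking values.
#'
#' @param pred,target numeric arrays of identical shape.
#' @param loss_mask logical array of the same shape with at least one
#'   `TRUE` entry.
#' @return scalar loss.
#' @export
masked_mse <- function(pred, target, loss_mask) {
  if (!identical(dim(pred), dim(target)) ||
      length(loss_mask) != length(pred))
    stopf("shape mismatch")
  if (!any(loss_mask)) stopf("empty loss mask: masked MSE undefined")
  mean((pred[loss_mask] - target[loss_mask])^2)
}

#' Plateau learning-rate scheduler
#'
#' Halves (`factor`) the learning rate whenever the validation loss has not
#' strictly improved for `patience` consecutive epochs; the wait counter
#' resets on improvement and after each reduction, and the rate never drops
#' below `floor`.
#'
#' @param lr initial learning rate.
#' @param patience plateau length in epochs.
#' @param factor multiplicative reduction factor in (0, 1).
#' @param floor lower bound on the learning rate.
#' @return scheduler state list; feed to [scheduler_step()].
#' @export
lr_scheduler <- function(lr, patience = 10, factor = 0.5, floor = 1e-7) {
  list(lr = lr, patience = patience, factor = factor, floor = floor,
       best = Inf, wait = 0L)
}

#' @rdname lr_scheduler
#' @param state scheduler state.
#' @param val_loss this epoch's validation loss.
#' @export
scheduler_step <- function(state, val_loss) {
  if (val_loss < state$best) {
    state$best <- val_loss
    state$wait <- 0L
  } else {
    state$wait <- state$wait + 1L
    if (state$wait >= state$patience) {
      state$lr <- max(state$floor, state$lr * state$factor)
      state$wait <- 0L
    }
  }
  state
}

# Coerce the accepted training-set representations to a list of matrices.
as_image_list <- function(x) {
  if (inherits(x, "phantom_dataset")) stopf("pass dataset splits, not the dataset")
  if (inherits(x, "phantom_sample")) x <- list(x)
  if (is.matrix(x)) x <- list(x)
  lapply(x, as_pixels)
}

sample_patch <- function(img, ph, pw) {
  H <- nrow(img); W <- ncol(img)
  if (ph > H || pw > W) stopf("patch %dx%d larger than image %dx%d", ph, pw, H, W)
  r0 <- sample.int(H - ph + 1L, 1L)
  c0 <- sample.int(W - pw + 1L, 1L)
  img[r0:(r0 + ph - 1L), c0:(c0 + pw - 1L)]
}

# Adam step on flat parameter vectors.
adam_step <- function(theta, g, st, lr, b1 = 0.9, b2 = 0.999, eps = 1e-8) {
  st$t <- st$t + 1L
  st$m <- b1 * st$m + (1 - b1) * g
  st$v <- b2 * st$v + (1 - b2) * g * g
  mhat <- st$m / (1 - b1^st$t)
  vhat <- st$v / (1 - b2^st$t)
  st$theta <- theta - lr * mhat / (sqrt(vhat) + eps)
  st
}

#' Deterministic validation loss
#'
#' Tiles every validation image with non-overlapping patches of the
#' configured size, builds mask plans from a fixed seed, and returns the
#' masked MSE pooled over all masked pixels. Repeated calls with the same
#' seed are identical, making the validation loss a deterministic function
#' of the weights.
#'
#' @param model a `"bsn_net"`.
#' @param val_set list of images (matrices, [bscan()]s or phantom samples).
#' @param config a [train_config()].
#' @param fixed_seed seed for the validation mask plans.
#' @return scalar masked MSE.
#' @export
validate <- function(model, val_set, config, fixed_seed = 1) {
  imgs <- as_image_list(val_set)
  if (length(imgs) == 0) stopf("empty validation set")
  ph <- config$patch_size[1]; pw <- config$patch_size[2]
  sse <- 0; npx <- 0
  tile_id <- 0L
  for (img in imgs) {
    nr <- nrow(img) %/% ph
    nc <- ncol(img) %/% pw
    if (nr == 0 || nc == 0) stopf("validation image smaller than patch size")
    for (i in seq_len(nr)) for (j in seq_len(nc)) {
      tile_id <- tile_id + 1L
      patch <- img[((i - 1) * ph + 1):(i * ph), ((j - 1) * pw + 1):(j * pw)]
      plan <- with_seed(derive_seed(fixed_seed, tile_id),
                        build_mask_plan(c(ph, pw), config$mask))
      if (nrow(plan$centers) == 0) next
      pred <- net_forward(model, apply_mask(patch, plan))
      err <- (pred - patch)[plan$loss_mask]
      sse <- sse + sum(err^2)
      npx <- npx + length(err)
    }
  }
  if (npx == 0) stopf("no masked pixels in validation tiling")
  sse / npx
}

#' Train a blind-spot denoising model
#'
#' Each step samples `batch_size` random patches from the training images,
#' augments them, masks them with fresh plans, and performs one Adam update
#' of the masked MSE between the prediction and the original (pre-masking)
#' values at the blind-spot centers. After each epoch the deterministic
#' validation loss drives the plateau scheduler, and the weights of the
#' best validation epoch are retained. Fully reproducible from
#' `config$seed`.
#'
#' @param model a `"bsn_net"` from [build_unet()].
#' @param train_set,val_set lists of images (matrices, [bscan()]s or
#'   phantom samples; the noisy field is used).
#' @param config a [train_config()].
#' @param verbose print one line per epoch.
#' @return object of class `"blindspot"`: the trained model (best epoch
#'   weights), `history` (epoch, train_loss, val_loss, lr), `best_epoch`,
#'   `spec` and `config`.
#' @export
train_model <- function(model, train_set, val_set, config = train_config(),
                        verbose = FALSE) {
  imgs <- as_image_list(train_set)
  if (length(imgs) == 0) stopf("empty training set")
  ph <- config$patch_size[1]; pw <- config$patch_size[2]
  for (img in imgs)
    if (ph > nrow(img) || pw > ncol(img))
      stopf("patch %dx%d larger than a training image", ph, pw)

  theta <- params_to_vec(model$params)
  ad <- list(theta = theta, m = numeric(length(theta)),
             v = numeric(length(theta)), t = 0L)
  sched <- lr_scheduler(config$initial_lr, config$plateau_patience,
                        config$lr_factor, config$lr_floor)
  history <- data.frame(epoch = integer(0), train_loss = numeric(0),
                        val_loss = numeric(0), lr = numeric(0))
  best <- list(epoch = 0L, val = Inf, theta = theta,
               buffers = model$buffers)

  set.seed(derive_seed(config$seed, 1L))
  for (epoch in seq_len(config$epochs)) {
    ep_loss <- 0
    for (step in seq_len(config$steps_per_epoch)) {
      xb <- array(0, dim = c(ph, pw, 1, config$batch_size))
      tb <- array(0, dim = c(ph, pw, 1, config$batch_size))
      mb <- array(FALSE, dim = c(ph, pw, 1, config$batch_size))
      for (b in seq_len(config$batch_size)) {
        patch <- sample_patch(imgs[[sample.int(length(imgs), 1L)]], ph, pw)
        patch <- augment(patch, config)
        plan <- build_mask_plan(c(ph, pw), config$mask)
        xb[, , 1, b] <- apply_mask(patch, plan)
        tb[, , 1, b] <- patch
        mb[, , 1, b] <- plan$loss_mask
      }
      nmask <- sum(mb)
      if (nmask == 0) next
      fw <- net_forward(model, xb, train = TRUE)
      model$buffers <- fw$buffers
      diffm <- (fw$y - tb) * mb
      loss <- sum(diffm^2) / nmask
      dy <- 2 * diffm / nmask
      grads <- net_backward(model, fw$cache, dy)
      ad <- adam_step(ad$theta, params_to_vec(grads), ad, sched$lr)
      model$params <- vec_to_params(model$params, ad$theta)
      ep_loss <- ep_loss + loss
    }
    tr_loss <- if (config$steps_per_epoch > 0)
      ep_loss / config$steps_per_epoch else NA_real_
    val_loss <- validate(model, val_set, config,
                         fixed_seed = derive_seed(config$seed, 999L))
    if (val_loss < best$val) {
      best <- list(epoch = epoch, val = val_loss, theta = ad$theta,
                   buffers = model$buffers)
    }
    sched <- scheduler_step(sched, val_loss)
    history <- rbind(history, data.frame(
      epoch = epoch, train_loss = tr_loss, val_loss = val_loss,
      lr = sched$lr))
    if (verbose)
      message(sprintf("epoch %3d  train %.6f  val %.6f  lr %.2e",
                      epoch, tr_loss, val_loss, sched$lr))
  }
  if (best$epoch > 0) {
    model$params <- vec_to_params(model$params, best$theta)
    model$buffers <- best$buffers
  }
  structure(list(model = model, spec = model$spec, config = config,
                 history = history, best_epoch = best$epoch),
            class = "blindspot")
}
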