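test_that("range remap moves bounds inward only, with exact linear arithmetic", {
  p <- matrix(0.5, 2, 2)
  expect_equal(blindspot:::remap_range(p, 0.2, -0.1)[1, 1], 0.2 + 0.5 * 0.7)
  expect_identical(blindspot:::remap_range(p, -0.3, 0.4), p)  # outward draws: unchanged
  expect_equal(range(blindspot:::remap_range(matrix(c(0, 1), 1), 0.2, -0.1)),
               c(0.2, 0.9))
  expect_error(blindspot:::remap_range(p, 1, -1), "empty")
})

test_that("about a quarter of augmentation draws leave the range unchanged", {
  cfg <- train_config("desk", flip_prob = 0)
  p <- matrix(c(0, 1), 1)
  unchanged <- blindspot:::with_seed(1, {
    mean(vapply(seq_len(10000), function(i)
      identical(augment(p, cfg), p), logical(1)))
  })
  se <- sqrt(0.25 * 0.75 / 10000)
  expect_lt(abs(unchanged - 0.25), 3 * se)
})

test_that("forced lateral flip is an involution", {
  cfg <- train_config("desk", flip_prob = 1, jitter_sigma = 0)
  p <- matrix(runif(12 * 16), 12, 16)
  once <- blindspot:::with_seed(2, augment(p, cfg))
  twice <- blindspot:::with_seed(3, augment(once, cfg))
  expect_false(identical(once, p))
  expect_identical(twice, p)
})

test_that("masked MSE averages squared error over center pixels only", {
  pr <- matrix(0, 4, 4); tg <- matrix(0, 4, 4)
  expect_equal(masked_mse(pr, tg, matrix(TRUE, 4, 4)), 0)
  pr[1, 1] <- 1; pr[2, 2] <- 3
  m <- matrix(FALSE, 4, 4); m[1, 1] <- m[2, 2] <- TRUE
  expect_equal(masked_mse(pr, tg, m), (1 + 9) / 2)
  # brute-force oracle on random inputs
  blindspot:::with_seed(4, {
    p2 <- matrix(rnorm(100), 10); t2 <- matrix(rnorm(100), 10)
    m2 <- matrix(runif(100) < 0.3, 10)
    m2[1, 1] <- TRUE
    acc <- 0; k <- 0
    for (i in 1:10) for (j in 1:10) if (m2[i, j]) {
      acc <- acc + (p2[i, j] - t2[i, j])^2; k <- k + 1
    }
    expect_equal(masked_mse(p2, t2, m2), acc / k)
  })
  expect_error(masked_mse(pr, tg, matrix(FALSE, 4, 4)), "empty")
})

test_that("a plateau of exactly 10 flat epochs triggers exactly one halving", {
  st <- lr_scheduler(1e-3, patience = 10, factor = 0.5)
  lrs <- numeric(0)
  for (v in rep(1, 11)) {
    st <- scheduler_step(st, v)
    lrs <- c(lrs, st$lr)
  }
  expect_equal(sum(diff(lrs) != 0), 1)     # one halving
  expect_equal(lrs[10], 1e-3)              # not before the 10th flat epoch
  expect_equal(lrs[11], 5e-4)
})

test_that("learning rate is non-increasing with ratio lr_factor, floored", {
  st <- lr_scheduler(1e-3, patience = 2, factor = 0.5, floor = 2e-4)
  vals <- c(1, 0.9, 0.95, 0.96, 0.8, 0.85, 0.9, 0.9, 0.9, 0.9, 0.9, 0.9)
  lrs <- numeric(0)
  for (v in vals) { st <- scheduler_step(st, v); lrs <- c(lrs, st$lr) }
  expect_true(all(diff(lrs) <= 0))
  ratios <- lrs[-1][diff(lrs) != 0] / lrs[-length(lrs)][diff(lrs) != 0]
  expect_true(all(abs(ratios - 0.5) < 1e-12 | lrs[-1][diff(lrs) != 0] == 2e-4))
  expect_gte(min(lrs), 2e-4)
})

test_that("zero-epoch training returns the initial weights and empty history", {
  m <- build_unet(net_spec(n = 2, seed = 5))
  imgs <- list(matrix(runif(32 * 32), 32, 32))
  cfg <- train_config("desk", epochs = 0, patch_size = c(16, 16))
  fit <- train_model(m, imgs, imgs, cfg)
  expect_equal(nrow(fit$history), 0)
  expect_equal(fit$best_epoch, 0L)
  expect_identical(blindspot:::params_to_vec(fit$model$params),
                   blindspot:::params_to_vec(m$params))
})

test_that("training is end-to-end deterministic for a fixed seed", {
  imgs <- blindspot:::with_seed(6,
    lapply(1:2, function(i) matrix(0.5 + 0.1 * rnorm(32 * 32), 32, 32)))
  cfg <- train_config("desk", epochs = 2, steps_per_epoch = 4, batch_size = 2,
                      patch_size = c(20, 20), seed = 42,
                      mask = mask_config(center_fraction = 0.01))
  run <- function() {
    fit <- train_model(build_unet(net_spec(n = 2, seed = 1)), imgs, imgs, cfg)
    list(h = fit$history, w = blindspot:::params_to_vec(fit$model$params))
  }
  a <- run(); b <- run()
  expect_identical(a$h, b$h)
  expect_identical(a$w, b$w)
  expect_true(all(diff(a$h$lr) <= 0))
})

test_that("validation loss is deterministic and matches a brute-force oracle", {
  imgs <- blindspot:::with_seed(7, list(matrix(runif(64 * 64), 64, 64)))
  cfg <- train_config("desk", patch_size = c(32, 32))
  m <- build_unet(net_spec(n = 2, residual = TRUE))
  expect_identical(validate(m, imgs, cfg, fixed_seed = 3),
                   validate(m, imgs, cfg, fixed_seed = 3))

  # identity model (zero weights + residual): prediction at a center equals
  # the replacement value, so the loss is the mean squared replacement
  # discrepancy at the centers, recomputable from the plans
  mz <- m
  mz$params <- rapply(mz$params, function(v) 0 * v, how = "replace")
  got <- validate(mz, imgs, cfg, fixed_seed = 9)
  img <- imgs[[1]]
  sse <- 0; npx <- 0; tile <- 0L
  for (i in 1:2) for (j in 1:2) {
    tile <- tile + 1L
    patch <- img[((i - 1) * 32 + 1):(i * 32), ((j - 1) * 32 + 1):(j * 32)]
    plan <- blindspot:::with_seed(blindspot:::derive_seed(9, tile),
                                  build_mask_plan(c(32, 32), cfg$mask))
    masked <- apply_mask(patch, plan)
    err <- (masked - patch)[plan$loss_mask]
    sse <- sse + sum(err^2); npx <- npx + length(err)
  }
  expect_equal(got, sse / npx)
})

test_that("an oracle predicting the clean signal scores the noise variance", {
  sp <- tiny_phantom_spec(noise_sigma = 0.1, sigma_ax = 0)
  smp <- corrupt(make_clean_bscan(sp), sp, seed = 10)
  # a denser mask keeps the sampling error of the 96x96 estimate small
  cfg <- train_config("desk", patch_size = c(32, 32),
                      mask = mask_config(center_fraction = 0.01))
  # evaluate the masked MSE a perfect oracle would achieve on this sample
  img <- as.matrix(smp$noisy); cln <- as.matrix(smp$clean)
  sse <- 0; npx <- 0; tile <- 0L
  for (i in 1:3) for (j in 1:3) {
    tile <- tile + 1L
    rows <- ((i - 1) * 32 + 1):(i * 32); cols <- ((j - 1) * 32 + 1):(j * 32)
    plan <- blindspot:::with_seed(blindspot:::derive_seed(1, tile),
                                  build_mask_plan(c(32, 32), cfg$mask))
    err <- (cln[rows, cols] - img[rows, cols])[plan$loss_mask]
    sse <- sse + sum(err^2); npx <- npx + length(err)
  }
  expect_lt(abs(sse / npx - sp$noise_sigma^2), 0.5 * sp$noise_sigma^2)
})

test_that("patches larger than the training images are refused", {
  m <- build_unet(net_spec(n = 2))
  imgs <- list(matrix(0.5, 32, 32))
  expect_error(train_model(m, imgs, imgs, train_config("desk")), "larger")
})
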