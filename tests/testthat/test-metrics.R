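test_that("PSNR closed forms", {
  A <- blindspot:::with_seed(1, matrix(runif(64 * 64) * 255, 64, 64))
  expect_identical(psnr(A, A), Inf)
  expect_equal(psnr(A + 16, A, R = 255), 10 * log10(255^2 / 256))
  expect_equal(psnr(A + 255, A, R = 255), 0)  # MSE = R^2 boundary
  expect_error(psnr(A, A[1:10, ]), "shape")
  # scale invariance: same dB on [0,1] floats with R = 1
  expect_equal(psnr(A / 255 + 16 / 255, A / 255, R = 1),
               psnr(A + 16, A, R = 255))
})

test_that("PSNR decreases monotonically as noise grows", {
  A <- blindspot:::with_seed(2, matrix(runif(128 * 128), 128, 128))
  noise <- blindspot:::with_seed(3, matrix(rnorm(128 * 128), 128, 128))
  p <- vapply(c(0.01, 0.03, 0.1, 0.3), function(s)
    psnr(A + s * noise, A, R = 1), numeric(1))
  expect_true(all(diff(p) < 0))
})

test_that("SSIM matches an independent reference implementation", {
  # fixture frozen against scikit-image structural_similarity
  # (gaussian_weights, sigma 1.5, win 11, use_sample_covariance = FALSE)
  A <- blindspot:::with_seed(77, matrix(runif(64 * 80), 64, 80))
  Y <- blindspot:::with_seed(77, {
    invisible(runif(64 * 80))
    pmin(pmax(A + matrix(rnorm(64 * 80, 0, 0.1), 64, 80), 0), 1)
  })
  expect_equal(ssim(Y, A, data_range = 1), 0.9444635013554085, tolerance = 1e-9)
  expect_equal(psnr(A, Y, R = 1), 20.42984156513386, tolerance = 1e-12)
})

test_that("SSIM basics: self-similarity, anticorrelation, range", {
  A <- blindspot:::with_seed(4, matrix(runif(48 * 48), 48, 48))
  expect_equal(ssim(A, A), 1)
  B <- matrix((outer(0:47, 0:47, "+") %% 2), 48, 48)
  expect_lt(ssim(1 - B, B), 0)
  for (k in 1:5) {
    Y <- blindspot:::with_seed(k, matrix(runif(48 * 48), 48, 48))
    s <- ssim(Y, A)
    expect_gte(s, -1); expect_lte(s, 1)
  }
  expect_error(ssim(A[1:8, 1:8], A[1:8, 1:8]), "window")
})

test_that("CNR hand case and zero-contrast case", {
  img <- matrix(0, 10, 10)
  s2 <- sqrt(2)
  img[1, 1:2] <- c(-s2, s2)        # background: mean 0, pop. var 2
  img[5, 1:2] <- c(2 - s2, 2 + s2) # foreground: mean 2, pop. var 2
  rois <- structure(list(foreground = list(c(5, 5, 1, 2)),
                         background = c(1, 1, 1, 2)), class = "roi_set")
  expect_equal(cnr(img, rois), 2 / sqrt(4))  # = 1
  img[5, 1:2] <- img[1, 1:2]
  expect_equal(cnr(img, rois), 0)
})

test_that("CNR equals a brute-force evaluation of the ROI formula", {
  sp <- tiny_phantom_spec()
  smp <- corrupt(make_clean_bscan(sp), sp, seed = 5)
  img <- as.matrix(smp$noisy)
  rois <- smp$rois
  pvar <- function(x) mean((x - mean(x))^2)
  bg <- img[rois$background[1]:rois$background[2],
            rois$background[3]:rois$background[4]]
  acc <- 0
  for (r in rois$foreground) {
    fg <- img[r[1]:r[2], r[3]:r[4]]
    acc <- acc + (mean(fg) - mean(bg)) / sqrt(pvar(fg) + pvar(bg))
  }
  expect_equal(cnr(img, rois), acc / length(rois$foreground))
})

test_that("CNR is invariant to offset and positive gain", {
  sp <- tiny_phantom_spec()
  smp <- corrupt(make_clean_bscan(sp), sp, seed = 6)
  img <- as.matrix(smp$noisy)
  base <- cnr(img, smp$rois)
  expect_equal(cnr(img + 3, smp$rois), base)
  expect_equal(cnr(img * 2.5, smp$rois), base)
  expect_equal(cnr(img * 1.7 + 0.4, smp$rois), base)
})

test_that("autocorrelation is normalized, symmetric, and small for white noise", {
  f <- blindspot:::with_seed(7, matrix(rnorm(256 * 256), 256, 256))
  ac <- autocorr2d(f, max_lag = 5)
  expect_equal(ac["0", "0"], 1)
  expect_identical(dim(ac), c(11L, 11L))
  expect_all_equal(ac, ac[11:1, 11:1])  # symmetry under lag negation
  off <- ac; off["0", "0"] <- 0
  expect_lt(max(abs(off)), 4 / sqrt(length(f)))
  expect_error(autocorr2d(matrix(1, 32, 32)), "constant")
})

test_that("evaluate: identical inputs give SSIM 1, zero dispersion, PSNR warning", {
  imgs <- blindspot:::with_seed(8, lapply(1:3, function(i)
    matrix(runif(96 * 96), 96, 96)))
  sp <- tiny_phantom_spec()
  rois <- corrupt(make_clean_bscan(sp), sp)$rois
  expect_warning(rep <- evaluate(imgs, imgs, rois, crop_margin = 8), "infinite")
  expect_true(all(rep$per_image$ssim == 1))
  expect_equal(rep$aggregate$two_sd[rep$aggregate$metric == "ssim"], 0)
})

test_that("evaluate aggregates mean and twice the sample SD", {
  # two images engineered to have CNR exactly 1 and 3 (gain invariance)
  img <- matrix(0, 20, 20)
  s2 <- sqrt(2)
  img[1, 1:2] <- c(-s2, s2)
  img[5, 1:2] <- c(2 - s2, 2 + s2)
  rois <- structure(list(foreground = list(c(5, 5, 1, 2)),
                         background = c(1, 1, 1, 2)), class = "roi_set")
  # second image: contrast 6 with the same variances -> CNR 3
  img2 <- img; img2[5, 1:2] <- c(6 - s2, 6 + s2)
  ref <- blindspot:::with_seed(9, matrix(runif(400), 20, 20))
  rep <- evaluate(list(img, img2), list(ref, ref), rois, crop_margin = 2)
  cnr_row <- rep$aggregate[rep$aggregate$metric == "cnr", ]
  expect_equal(cnr_row$mean, 2)
  expect_equal(cnr_row$two_sd, 2 * sqrt(2))
})

test_that("evaluate is permutation-invariant and warns for a single image", {
  sp <- tiny_phantom_spec()
  items <- lapply(1:3, function(i) corrupt(make_clean_bscan(sp), sp, seed = i))
  den <- lapply(items, function(s) as.matrix(s$noisy))
  ref <- lapply(items, function(s) as.matrix(s$clean))
  rois <- lapply(items, `[[`, "rois")
  a <- evaluate(den, ref, rois, crop_margin = 8)
  perm <- c(3, 1, 2)
  b <- evaluate(den[perm], ref[perm], rois[perm], crop_margin = 8)
  expect_equal(a$aggregate, b$aggregate)
  w <- testthat::capture_warnings(evaluate(den[1], ref[1], rois[1], crop_margin = 8))
  expect_true(any(grepl("single image", w)))
  expect_error(evaluate(list(), list(), rois), "empty")
})

test_that("frame averaging improves CNR on phantom evaluation items", {
  ds <- make_dataset(0, 0, 3, phantom_spec(), seed = 10, m = 25)
  for (it in ds$eval) {
    expect_gt(cnr(it$average, it$rois), cnr(it$noisy, it$rois))
  }
})

test_that("metric report CSV round-trips per-image and aggregate rows", {
  sp <- tiny_phantom_spec()
  s1 <- corrupt(make_clean_bscan(sp), sp, seed = 11)
  s2 <- corrupt(make_clean_bscan(sp), sp, seed = 12)
  rep <- evaluate(list(as.matrix(s1$noisy), as.matrix(s2$noisy)),
                  list(as.matrix(s1$clean), as.matrix(s2$clean)),
                  list(s1$rois, s2$rois), crop_margin = 8)
  tmp <- withr::local_tempfile(fileext = ".csv")
  write_metric_report(rep, tmp)
  back <- read.csv(tmp)
  expect_equal(nrow(back), 4)
  expect_equal(back$psnr[back$image == "mean"],
               rep$aggregate$mean[rep$aggregate$metric == "psnr"])
})
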