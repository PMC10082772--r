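# Evaluation protocol: PSNR, SSIM, ROI-based CNR, 2D noise autocorrelation,
# and mean +/- 2 sample-SD aggregation.

#' Peak signal-to-noise ratio
#'
#' `10 * log10(R^2 / MSE(Y, A))` in dB, with `R` the maximum intensity
#' range (255 for 8-bit data, 1 for normalized floats -- the dB value is
#' identical as long as images and `R` share a scale). Identical images
#' yield `Inf`.
#'
#' @param Y,A images of equal shape (estimate and reference).
#' @param R intensity range (> 0).
#' @return PSNR in dB.
#' @export
psnr <- function(Y, A, R = 255) {
  Y <- as_pixels(Y); A <- as_pixels(A)
  if (!identical(dim(Y), dim(A))) stopf("psnr: shape mismatch")
  if (R <= 0) stopf("psnr: R must be > 0")
  mse <- mean((Y - A)^2)
  if (mse == 0) return(Inf)
  10 * log10(R^2 / mse)
}

#' Structural similarity index (mean SSIM)
#'
#' Standard SSIM with a Gaussian window (size 11, sigma 1.5) and stability
#' constants `K1 = 0.01`, `K2 = 0.03` relative to `data_range`; local
#' statistics use reflection padding and the mean is taken over the map
#' cropped by the window half-width.
#'
#' @param Y,A images of equal shape.
#' @param data_range value range of the data (1 for normalized floats,
#'   255 for 8-bit).
#' @param K1,K2 stability constants.
#' @param win_size,win_sigma Gaussian window size (odd) and width.
#' @return mean SSIM in `[-1, 1]`.
#' @export
ssim <- function(Y, A, data_range = 1, K1 = 0.01, K2 = 0.03,
                 win_size = 11, win_sigma = 1.5) {
  Y <- as_pixels(Y); A <- as_pixels(A)
  if (!identical(dim(Y), dim(A))) stopf("ssim: shape mismatch")
  if (win_size %% 2 == 0) stopf("ssim: win_size must be odd")
  if (any(dim(Y) < win_size)) stopf("ssim: window larger than image")
  r <- (win_size - 1) / 2
  g <- exp(-(seq(-r, r))^2 / (2 * win_sigma^2))
  g <- g / sum(g)
  filt <- function(m) {
    reflect <- function(n) c(rev(seq_len(r) + 1L), seq_len(n),
                             n - seq_len(r))
    pad <- m[reflect(nrow(m)), reflect(ncol(m)), drop = FALSE]
    out <- matrix(0, nrow(m), ncol(m))
    tmp <- matrix(0, nrow(m), ncol(pad))
    for (t in seq_along(g))
      tmp <- tmp + g[t] * pad[(t - 1L) + seq_len(nrow(m)), , drop = FALSE]
    for (t in seq_along(g))
      out <- out + g[t] * tmp[, (t - 1L) + seq_len(ncol(m)), drop = FALSE]
    out
  }
  C1 <- (K1 * data_range)^2
  C2 <- (K2 * data_range)^2
  mu_x <- filt(Y); mu_y <- filt(A)
  sxx <- filt(Y * Y) - mu_x^2
  syy <- filt(A * A) - mu_y^2
  sxy <- filt(Y * A) - mu_x * mu_y
  map <- ((2 * mu_x * mu_y + C1) * (2 * sxy + C2)) /
    ((mu_x^2 + mu_y^2 + C1) * (sxx + syy + C2))
  core <- map[(r + 1):(nrow(map) - r), (r + 1):(ncol(map) - r)]
  mean(core)
}

roi_pixels <- function(img, rect) img[rect[1]:rect[2], rect[3]:rect[4]]

#' Contrast-to-noise ratio over an ROI set
#'
#' Mean over the foreground ROIs of
#' `(mu_f - mu_b) / sqrt(sigma_f^2 + sigma_b^2)` against the single
#' background ROI. ROI statistics use the population convention
#' (`N` denominator).
#'
#' @param Y image.
#' @param rois an ROI set (see [place_rois()]).
#' @return CNR score.
#' @export
cnr <- function(Y, rois) {
  Y <- as_pixels(Y)
  pvar <- function(x) mean((x - mean(x))^2)
  bg <- roi_pixels(Y, rois$background)
  if (length(bg) < 2) stopf("cnr: ROIs need >= 2 pixels")
  mu_b <- mean(bg); var_b <- pvar(bg)
  vals <- vapply(rois$foreground, function(r) {
    fg <- roi_pixels(Y, r)
    if (length(fg) < 2) stopf("cnr: ROIs need >= 2 pixels")
    var_f <- pvar(fg)
    if (var_f + var_b == 0) stopf("cnr: zero variance in an ROI pair")
    (mean(fg) - mu_b) / sqrt(var_f + var_b)
  }, numeric(1))
  mean(vals)
}

#' Normalized 2D autocorrelation of a field
#'
#' Circular (FFT-based) autocorrelation of the mean-subtracted field,
#' normalized to 1 at lag (0, 0) and symmetric under lag negation. Returns
#' the `(2 max_lag + 1)^2` window centered at lag 0 with dimnames giving
#' the lags.
#'
#' @param field numeric matrix (non-constant).
#' @param max_lag maximum lag returned in each dimension.
#' @return autocorrelation matrix.
#' @export
autocorr2d <- function(field, max_lag = 10) {
  x <- as_pixels(field)
  H <- nrow(x); W <- ncol(x)
  if (2 * max_lag >= min(H, W)) stopf("field too small for max_lag")
  x <- x - mean(x)
  if (all(x == 0)) stopf("constant field has no autocorrelation")
  fx <- fft(x)
  ac <- Re(fft(fx * Conj(fx), inverse = TRUE)) / length(x)
  ac <- ac / ac[1, 1]
  lag <- -max_lag:max_lag
  out <- ac[((lag %% H) + 1), ((lag %% W) + 1)]
  dimnames(out) <- list(axial = lag, lateral = lag)
  out
}

#' Evaluate a set of denoised images against references
#'
#' PSNR and SSIM are computed on a central crop (to mirror the protocol of
#' discarding registration borders), CNR on the full image over its ROI
#' set. Aggregates are the plain mean over images and twice the sample
#' standard deviation (`n - 1` denominator). Infinite PSNR values
#' (identical images) are excluded from the PSNR aggregate with a warning.
#'
#' @param denoised list of images.
#' @param reference list of matching reference images.
#' @param rois single ROI set or list of ROI sets (one per image).
#' @param crop_margin pixels trimmed from each side for PSNR/SSIM.
#' @param data_range intensity range of the data.
#' @return object of class `"metric_report"`: `per_image` data frame,
#'   `aggregate` data frame (mean and `two_sd` per metric), and the
#'   parameter record.
#' @export
evaluate <- function(denoised, reference, rois, crop_margin = 16,
                     data_range = 1) {
  if (!is.list(denoised)) denoised <- list(denoised)
  if (!is.list(reference)) reference <- list(reference)
  n <- length(denoised)
  if (n == 0) stopf("evaluate: empty image set")
  if (length(reference) != n) stopf("evaluate: set size mismatch")
  roi_list <- if (inherits(rois, "roi_set")) rep(list(rois), n) else rois
  crop <- function(m) {
    m <- as_pixels(m)
    m[(crop_margin + 1):(nrow(m) - crop_margin),
      (crop_margin + 1):(ncol(m) - crop_margin)]
  }
  per <- data.frame(image = seq_len(n), psnr = NA_real_, ssim = NA_real_,
                    cnr = NA_real_)
  for (i in seq_len(n)) {
    per$psnr[i] <- psnr(crop(denoised[[i]]), crop(reference[[i]]),
                        R = data_range)
    per$ssim[i] <- ssim(crop(denoised[[i]]), crop(reference[[i]]),
                        data_range = data_range)
    per$cnr[i] <- cnr(denoised[[i]], roi_list[[i]])
  }
  agg_of <- function(v, name) {
    if (name == "psnr" && any(is.infinite(v))) {
      warning("excluding infinite PSNR values from the aggregate")
      v <- v[is.finite(v)]
    }
    if (length(v) == 1) {
      warning("single image: dispersion reported as 0")
      return(c(mean = v, two_sd = 0))
    }
    c(mean = mean(v), two_sd = 2 * sd(v))
  }
  agg <- do.call(rbind, lapply(c("psnr", "ssim", "cnr"), function(mname)
    data.frame(metric = mname, t(agg_of(per[[mname]], mname)))))
  structure(list(per_image = per, aggregate = agg,
                 params = list(crop_margin = crop_margin,
                               data_range = data_range,
                               ssim = list(K1 = 0.01, K2 = 0.03,
                                           win_size = 11, win_sigma = 1.5),
                               roi_variance = "population (N)",
                               aggregate_sd = "sample (n-1), reported as 2*SD")),
            class = "metric_report")
}

#' @export
print.metric_report <- function(x, ...) {
  cat(sprintf("metric_report over %d image(s)\n", nrow(x$per_image)))
  for (i in seq_len(nrow(x$aggregate)))
    cat(sprintf("  %-5s %8.4f +/- %.4f (2 SD)\n",
                x$aggregate$metric[i], x$aggregate$mean[i],
                x$aggregate$two_sd[i]))
  invisible(x)
}

#' Write a metric report as CSV
#'
#' One row per image plus aggregate rows (`image = "mean"` / `"two_sd"`).
#'
#' @param report a `"metric_report"`.
#' @param path output CSV path.
#' @export
write_metric_report <- function(report, path) {
  per <- report$per_image
  per$image <- as.character(per$image)
  agg <- data.frame(image = c("mean", "two_sd"),
                    psnr = c(report$aggregate$mean[1], report$aggregate$two_sd[1]),
                    ssim = c(report$aggregate$mean[2], report$aggregate$two_sd[2]),
                    cnr = c(report$aggregate$mean[3], report$aggregate$two_sd[3]))
  write.csv(rbind(per, agg), path, row.names = FALSE)
  invisible(path)
}
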