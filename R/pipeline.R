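# Streaming-buffer inference path: lateral split into pseudo-batch channels,
# 20-A-scan padding (edge replication at outer edges, true continuation at
# interior cuts), pseudo-batched inference, overlap-discarding recombination,
# black-level subtraction, and the Gaussian reference filter.

#' Buffer-pipeline specification
#'
#' @param sub_buffer_count lateral splits = pseudo-batch channels.
#' @param pad lateral padding in A-scans per side; must cover half the
#'   model's receptive-field extent.
#' @param black_level gray value subtracted (with clipping at zero) after
#'   denoising, on the same scale as the buffer.
#' @return object of class `"buffer_spec"`.
#' @export
buffer_spec <- function(sub_buffer_count = 4, pad = 20, black_level = 0) {
  stopifnot(is_count(sub_buffer_count), sub_buffer_count >= 1,
            is_count(pad), black_level >= 0)
  structure(list(sub_buffer_count = as.integer(sub_buffer_count),
                 pad = as.integer(pad), black_level = black_level),
            class = "buffer_spec")
}

#' Split a buffer laterally and pad each sub-buffer
#'
#' Channel `i` carries core columns `((i-1) * W/k, i * W/k]` plus `pad`
#' columns on each side: the true neighboring columns where they exist
#' (interior cuts and pads reaching into the buffer), the first/last column
#' replicated at the two outer edges. Reassembling the cores restores the
#' buffer exactly.
#'
#' @param buffer numeric matrix (axial x lateral); the lateral size must be
#'   divisible by `sub_buffer_count` (pre-pad explicitly otherwise --
#'   silent geometry changes are refused).
#' @param spec a [buffer_spec()].
#' @return `(H, W/k + 2 pad, k)` array.
#' @export
split_and_pad <- function(buffer, spec = buffer_spec()) {
  x <- as_pixels(buffer)
  H <- nrow(x); W <- ncol(x)
  k <- spec$sub_buffer_count
  if (W %% k != 0)
    stopf("lateral size %d not divisible by %d sub-buffers", W, k)
  wc <- W %/% k
  p <- spec$pad
  # replicate outer edges once; interior pads then read true continuations
  ext <- x[, c(rep(1L, p), seq_len(W), rep(W, p)), drop = FALSE]
  out <- array(0, dim = c(H, wc + 2L * p, k))
  for (i in seq_len(k)) {
    out[, , i] <- ext[, ((i - 1L) * wc + 1L):((i - 1L) * wc + wc + 2L * p)]
  }
  out
}

# Inverse of split_and_pad: drop pads, concatenate cores.
recombine <- function(stack, spec) {
  p <- spec$pad
  wc <- dim(stack)[2] - 2L * p
  k <- dim(stack)[3]
  out <- matrix(0, dim(stack)[1], wc * k)
  for (i in seq_len(k))
    out[, ((i - 1L) * wc + 1L):(i * wc)] <- stack[, (p + 1L):(p + wc), i]
  out
}

#' Denoise a buffer through the pseudo-batch pipeline
#'
#' Splits the buffer into `sub_buffer_count` padded channels, runs one
#' inference pass of the pseudo-batched model, discards the overlapping
#' pad regions, and recombines the cores, restoring the original buffer
#' size. Provided the padding covers half the receptive field, the result
#' matches single-pass whole-buffer inference (with replicated edge
#' padding) except for floating-point round-off. Buffers are expected in
#' the log-intensity domain *before* black-level subtraction.
#'
#' @param buffer numeric matrix (axial x lateral).
#' @param model4 a pseudo-batched model from [export_pseudobatch()] with
#'   `in_channels == sub_buffer_count`.
#' @param spec a [buffer_spec()].
#' @param precision `"single"` or `"half"` (see [net_forward()]).
#' @return the denoised buffer, same dimensions as the input.
#' @export
denoise_buffer <- function(buffer, model4, spec = buffer_spec(),
                           precision = c("single", "half")) {
  precision <- match.arg(precision)
  if (!inherits(model4, "bsn_net")) stopf("model4 must be a bsn_net")
  if (model4$in_channels != spec$sub_buffer_count)
    stopf("model has %d channels but spec asks for %d sub-buffers",
          model4$in_channels, spec$sub_buffer_count)
  half_rf <- rf_theoretical(model4$spec) %/% 2L
  if (spec$pad < half_rf)
    stopf("pad %d below the receptive half-width %d: seams would be silent",
          spec$pad, half_rf)
  stack <- split_and_pad(buffer, spec)
  d <- dim(stack)
  x <- array(stack, dim = c(d[1], d[2], d[3], 1))
  y <- net_forward(model4, x, precision = precision)
  recombine(array(y, dim = d), spec)
}

#' Whole-buffer single-pass inference (reference path)
#'
#' Pads the buffer laterally by `pad` replicated columns on each side, runs
#' the single-channel model once, and crops; the oracle the pseudo-batch
#' pipeline is validated against.
#'
#' @param buffer numeric matrix.
#' @param model single-channel `"bsn_net"`.
#' @param pad lateral padding in A-scans.
#' @param precision `"single"` or `"half"`.
#' @return denoised buffer of the input size.
#' @export
denoise_whole <- function(buffer, model, pad = 20,
                          precision = c("single", "half")) {
  precision <- match.arg(precision)
  x <- as_pixels(buffer)
  W <- ncol(x)
  ext <- x[, c(rep(1L, pad), seq_len(W), rep(W, pad)), drop = FALSE]
  y <- net_forward(model, ext, precision = precision)
  y[, (pad + 1L):(pad + W), drop = FALSE]
}

#' Gaussian reference filter
#'
#' Isotropic Gaussian blur with the kernel truncated at two standard
#' deviations (side `2 * ceiling(2 sigma) + 1`, i.e. 21x21 for the default
#' `sigma = 5`), renormalized to unit sum, applied as a 'same'-size
#' separable convolution with edge replication.
#'
#' @param image numeric matrix.
#' @param sigma standard deviation in pixels (> 0).
#' @return the filtered matrix.
#' @export
gaussian_baseline <- function(image, sigma = 5) {
  if (sigma <= 0) stopf("sigma must be > 0")
  x <- as_pixels(image)
  r <- ceiling(2 * sigma)
  g <- exp(-(seq(-r, r))^2 / (2 * sigma^2))
  g <- g / sum(g)
  conv1 <- function(m, along_rows) {
    n <- if (along_rows) nrow(m) else ncol(m)
    idx_clamp <- function(i) pmin(pmax(i, 1L), n)
    out <- 0 * m
    for (t in seq_along(g)) {
      sh <- t - 1L - r
      idx <- idx_clamp(seq_len(n) + sh)
      out <- out + g[t] * (if (along_rows) m[idx, , drop = FALSE]
                           else m[, idx, drop = FALSE])
    }
    out
  }
  conv1(conv1(x, TRUE), FALSE)
}

#' Kernel of the Gaussian reference filter
#'
#' @param sigma standard deviation in pixels.
#' @return the truncated, renormalized 2D kernel matrix.
#' @export
gaussian_kernel <- function(sigma = 5) {
  r <- ceiling(2 * sigma)
  g <- exp(-(seq(-r, r))^2 / (2 * sigma^2))
  k <- outer(g, g)
  k / sum(k)
}

#' Subtract the black level
#'
#' Subtracts a fixed gray value and clips at zero, cropping the noise
#' floor; in the deployment pipeline this happens *after* denoising.
#'
#' @param image numeric matrix.
#' @param level black level (>= 0), same scale as the image.
#' @return `pmax(image - level, 0)`.
#' @export
subtract_black_level <- function(image, level) {
  if (level < 0) stopf("level must be >= 0")
  pmax(as_pixels(image) - level, 0)
}
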