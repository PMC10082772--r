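# Synthetic layered B-scan phantoms.
#
# A phantom is a piecewise-constant "retina-like" stack of wavy layers in the
# log-intensity domain, corrupted by zero-mean additive Gaussian noise with a
# short axial correlation length -- the statistical structure that log-scaled
# speckle is assumed to have, and the one the structured 7x1 axial mask is
# designed to hide.

#' Construct a B-scan image object
#'
#' A B-scan is a 2D matrix of log-intensity values; rows are the axial
#' (depth) dimension, columns are consecutive A-scans. Values are kept as
#' floats in a nominal normalized range (default `[0, 1]`); quantization to
#' 8 bit happens only on export.
#'
#' @param pixels numeric matrix (axial x lateral), finite values only.
#' @param value_range nominal `c(lo, hi)` of the normalized representation.
#' @return a matrix of class `"bscan"` with a `value_range` attribute.
#' @export
bscan <- function(pixels, value_range = c(0, 1)) {
  pixels <- as.matrix(pixels)
  if (!all(is.finite(pixels))) stopf("bscan: pixels must be finite")
  if (length(value_range) != 2 || value_range[1] >= value_range[2])
    stopf("bscan: invalid value_range")
  structure(pixels, value_range = value_range, class = c("bscan", "matrix", "array"))
}

#' @export
as.matrix.bscan <- function(x, ...) as_pixels(x)

#' @export
print.bscan <- function(x, ...) {
  vr <- attr(x, "value_range")
  cat(sprintf("bscan %dx%d (axial x lateral), range [%g, %g]\n",
              nrow(x), ncol(x), vr[1], vr[2]))
  invisible(x)
}

as_pixels <- function(x) {
  if (inherits(x, "phantom_sample")) x <- x$noisy
  x <- unclass(x)
  attr(x, "value_range") <- NULL
  attr(x, "boundaries") <- NULL
  as.matrix(x)
}

#' Phantom generator specification
#'
#' Defines the layered clean structure and the noise model. Layer boundaries
#' are sums of sinusoids around evenly spaced base depths, with amplitudes
#' bounded so that boundaries stay strictly ordered at every column. Noise is
#' a white Gaussian field smoothed by a separable Gaussian kernel with axial
#' correlation length `sigma_ax` and lateral length `sigma_lat` (in pixels),
#' rescaled to the marginal `noise_sigma` and mean-centered.
#'
#' The default `sigma_ax = 1.5` px makes the noise correlation negligible
#' beyond about +/-3 px, matching the rationale for masking 7x1 axial strips;
#' `sigma_lat = 0` leaves A-scans mutually independent.
#'
#' @param rows,cols image size (axial x lateral).
#' @param n_layers number of tissue layers (the region above the first
#'   boundary is background at `floor`).
#' @param reflectivities per-layer log-reflectivity in `[floor, 1]`; default
#'   is an alternating light/dark pattern.
#' @param floor background log-intensity level.
#' @param amp_frac boundary waviness amplitude as a fraction of the mean
#'   layer gap (must stay below 0.25 to guarantee ordering).
#' @param n_harmonics sinusoid count per boundary.
#' @param membrane add a thin bright membrane under the first boundary.
#' @param noise_sigma marginal noise standard deviation (log domain, on the
#'   `[0, 1]` scale).
#' @param sigma_ax,sigma_lat Gaussian correlation lengths in pixels (>= 0).
#' @param seed RNG seed for the clean geometry.
#' @return object of class `"phantom_spec"`.
#' @export
phantom_spec <- function(rows = 256, cols = 256, n_layers = 6,
                         reflectivities = NULL, floor = 0.1,
                         amp_frac = 0.2, n_harmonics = 3, membrane = TRUE,
                         noise_sigma = 0.1, sigma_ax = 1.5, sigma_lat = 0,
                         seed = 1) {
  if (!is_count(n_layers)) stopf("n_layers must be a non-negative integer")
  if (is.null(reflectivities) && n_layers > 0) {
    pal <- c(0.35, 0.70, 0.50, 0.85, 0.40, 0.75, 0.55, 0.90)
    reflectivities <- rep_len(pal, n_layers)
  }
  if (n_layers > 0 &&
      (length(reflectivities) != n_layers ||
       any(reflectivities < floor) || any(reflectivities > 1)))
    stopf("reflectivities must have length n_layers and lie in [floor, 1]")
  if (noise_sigma < 0 || sigma_ax < 0 || sigma_lat < 0)
    stopf("noise_sigma and correlation lengths must be >= 0")
  if (amp_frac < 0 || amp_frac >= 0.25)
    stopf("amp_frac must be in [0, 0.25) to keep boundaries ordered")
  structure(list(rows = rows, cols = cols, n_layers = n_layers,
                 reflectivities = reflectivities, floor = floor,
                 amp_frac = amp_frac, n_harmonics = n_harmonics,
                 membrane = membrane, noise_sigma = noise_sigma,
                 sigma_ax = sigma_ax, sigma_lat = sigma_lat, seed = seed),
            class = "phantom_spec")
}

# Boundary depth curves: L x W matrix, strictly increasing down each column.
phantom_boundaries <- function(spec) {
  L <- spec$n_layers
  W <- spec$cols
  if (L == 0) return(matrix(numeric(0), 0, W))
  with_seed(derive_seed(spec$seed, 11L), {
    top <- 0.15 * spec$rows
    bottom <- 0.92 * spec$rows
    gap <- (bottom - top) / L
    base <- top + (seq_len(L) - 1) * gap + runif(L, 0.25, 0.75) * gap
    b <- matrix(0, L, W)
    xs <- (seq_len(W) - 1) / W
    for (l in seq_len(L)) {
      amps <- runif(spec$n_harmonics)
      amps <- amps / sum(amps) * spec$amp_frac * gap
      cycles <- runif(spec$n_harmonics, 0.5, 2)
      phases <- runif(spec$n_harmonics, 0, 2 * pi)
      wave <- rep(0, W)
      for (j in seq_len(spec$n_harmonics))
        wave <- wave + amps[j] * sin(2 * pi * cycles[j] * xs + phases[j])
      b[l, ] <- base[l] + wave
    }
    b
  })
}

# Map a column's boundary depths + a row index to a clean value.
layer_value <- function(spec, label) {
  ifelse(label == 0, spec$floor, spec$reflectivities[pmax(label, 1)])
}

#' Generate the clean (noise-free) phantom B-scan
#'
#' Piecewise-constant reflectivity per layer with smooth wavy boundaries;
#' deterministic for a fixed `spec$seed`. The boundary curves are attached as
#' the `"boundaries"` attribute (one row per boundary, one column per A-scan)
#' so that downstream ROI placement and auditing can re-derive the layer
#' label of any pixel.
#'
#' @param spec a [phantom_spec()].
#' @return a [bscan()] with a `"boundaries"` attribute.
#' @export
make_clean_bscan <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  H <- spec$rows; W <- spec$cols
  b <- phantom_boundaries(spec)
  img <- matrix(spec$floor, H, W)
  if (spec$n_layers > 0) {
    rows <- seq_len(H)
    for (c in seq_len(W)) {
      lab <- findInterval(rows, b[, c])
      img[, c] <- layer_value(spec, lab)
      if (isTRUE(spec$membrane)) {
        m0 <- b[1, c]
        img[rows >= m0 & rows < m0 + 2, c] <- 0.98
      }
    }
  }
  out <- bscan(img)
  attr(out, "boundaries") <- b
  out
}

# Correlated zero-mean Gaussian noise field with marginal sd `sigma`.
# White noise is circularly convolved with normalized separable Gaussian
# kernels (so the field stays stationary and the autocorrelation has the
# closed form of the kernel's self-correlation), rescaled to the target
# marginal sigma, then mean-centered.
correlated_noise <- function(H, W, sigma, sigma_ax = 0, sigma_lat = 0) {
  field <- matrix(rnorm(H * W), H, W)
  scale2 <- 1
  circ_smooth <- function(x, g, along_rows) {
    r <- (length(g) - 1) / 2
    out <- 0 * x
    n <- if (along_rows) nrow(x) else ncol(x)
    for (t in seq_along(g)) {
      sh <- t - 1 - r
      idx <- ((seq_len(n) - 1 + sh) %% n) + 1
      out <- out + g[t] * (if (along_rows) x[idx, , drop = FALSE]
                           else x[, idx, drop = FALSE])
    }
    out
  }
  gauss_kernel_1d <- function(s) {
    r <- max(1L, ceiling(5 * s))
    g <- exp(-(seq(-r, r))^2 / (2 * s^2))
    g / sum(g)
  }
  if (sigma_ax > 0) {
    g <- gauss_kernel_1d(sigma_ax)
    field <- circ_smooth(field, g, TRUE)
    scale2 <- scale2 * sum(g^2)
  }
  if (sigma_lat > 0) {
    g <- gauss_kernel_1d(sigma_lat)
    field <- circ_smooth(field, g, FALSE)
    scale2 <- scale2 * sum(g^2)
  }
  field <- field * (sigma / sqrt(scale2))
  field - mean(field)
}

#' Corrupt a clean B-scan with the phantom noise model
#'
#' Adds a zero-mean Gaussian field with the correlation structure defined in
#' `spec` (`v = s + n` holds exactly by construction). Values are not clipped
#' internally; clipping happens only at 8-bit export.
#'
#' @param clean a clean [bscan()] (typically from [make_clean_bscan()]).
#' @param spec the [phantom_spec()] (noise parameters are read from it).
#' @param seed RNG seed for the noise realization.
#' @return object of class `"phantom_sample"` with fields `clean`, `noise`,
#'   `noisy`, `spec` and (when boundaries are available) `rois`.
#' @export
corrupt <- function(clean, spec, seed = spec$seed) {
  px <- as_pixels(clean)
  noise <- if (spec$noise_sigma == 0) {
    matrix(0, nrow(px), ncol(px))
  } else {
    with_seed(derive_seed(seed, 23L),
              correlated_noise(nrow(px), ncol(px), spec$noise_sigma,
                               spec$sigma_ax, spec$sigma_lat))
  }
  b <- attr(clean, "boundaries")
  rois <- if (!is.null(b) && nrow(b) > 0)
    tryCatch(place_rois(b, dim(px)), error = function(e) NULL)
  structure(list(clean = clean, noise = noise,
                 noisy = bscan(px + noise), spec = spec, rois = rois),
            class = "phantom_sample")
}

#' Place the 14+1 evaluation ROIs on a phantom
#'
#' Programmatically places 14 foreground rectangles inside tissue layers
#' (cycling through layers and lateral bands) and one background rectangle
#' above the first boundary. Rectangles are stored 1-based inclusive as
#' `c(row0, row1, col0, col1)`; CSV serialization converts to 0-based
#' half-open intervals.
#'
#' @param boundaries L x W matrix of boundary depths.
#' @param dim image `c(rows, cols)`.
#' @param n_fg number of foreground ROIs.
#' @param size square ROI side length in pixels.
#' @return object of class `"roi_set"`: `list(foreground = <list>,
#'   background = <rect>)`.
#' @export
place_rois <- function(boundaries, dim, n_fg = 14, size = 10) {
  H <- dim[1]; W <- dim[2]
  L <- nrow(boundaries)
  if (L == 0) stopf("cannot place ROIs without layers")
  bg_top <- 2
  bg_bot <- bg_top + size - 1
  if (bg_bot >= min(boundaries[1, ]) - 1)
    stopf("image too small to host the background ROI above the first boundary")
  bg_c0 <- max(1, floor(W / 2 - size / 2))
  background <- c(bg_top, bg_bot, bg_c0, bg_c0 + size - 1)

  n_bands <- ceiling(n_fg / L)
  fg <- vector("list", n_fg)
  for (i in seq_len(n_fg)) {
    l <- ((i - 1) %% L) + 1
    band <- (i - 1) %/% L
    # preferred lateral band for this ROI; scan nearby starts until the
    # layer is locally thick enough to take a size x size rectangle
    pref <- round((band + 0.5) * W / n_bands - size / 2)
    starts <- unique(pmin(pmax(round(pref + size *
      (seq_len(2 * ceiling(W / size)) %/% 2) *
      rep_len(c(1, -1), 2 * ceiling(W / size))), 1), W - size + 1))
    placed <- FALSE
    for (c0 in starts) {
      cols <- c0:(c0 + size - 1)
      top_lim <- ceiling(max(boundaries[l, cols])) + 2
      bot_lim <- if (l < L) floor(min(boundaries[l + 1, cols])) - 2 else H - 2
      # skip the 2-px membrane band under the first boundary
      if (l == 1) top_lim <- top_lim + 2
      if (bot_lim - top_lim + 1 >= size) {
        r0 <- floor((top_lim + bot_lim - size + 1) / 2)
        fg[[i]] <- c(r0, r0 + size - 1, c0, c0 + size - 1)
        placed <- TRUE
        break
      }
    }
    if (!placed)
      stopf("image too small to host %d disjoint ROIs", n_fg + 1)
  }
  structure(list(foreground = fg, background = background),
            class = "roi_set")
}

#' Validate an ROI set against an image size
#'
#' Checks bounds, the foreground count, and disjointness of the background
#' rectangle from every foreground rectangle.
#'
#' @param rois a `"roi_set"`.
#' @param dim image `c(rows, cols)`.
#' @param n_fg expected number of foreground ROIs.
#' @return `TRUE` invisibly; errors otherwise.
#' @export
validate_rois <- function(rois, dim, n_fg = 14) {
  in_bounds <- function(r) r[1] >= 1 && r[2] <= dim[1] && r[3] >= 1 &&
    r[4] <= dim[2] && r[1] <= r[2] && r[3] <= r[4]
  overlap <- function(a, b) a[1] <= b[2] && b[1] <= a[2] &&
    a[3] <= b[4] && b[3] <= a[4]
  if (length(rois$foreground) != n_fg)
    stopf("expected %d foreground ROIs", n_fg)
  if (!in_bounds(rois$background)) stopf("background ROI out of bounds")
  for (r in rois$foreground) {
    if (!in_bounds(r)) stopf("foreground ROI out of bounds")
    if (overlap(r, rois$background))
      stopf("background ROI overlaps a foreground ROI")
  }
  invisible(TRUE)
}

#' Generate a phantom dataset with train/val/eval splits
#'
#' Every item has its own clean geometry and noise realization (seeds are
#' disjoint across splits and items). Evaluation items additionally carry an
#' `m`-frame averaged reference (mean of `m` independent noisy realizations
#' of the same clean image, emulating registered-and-averaged ground truth)
#' and the 14+1 ROI set.
#'
#' @param n_train,n_val,n_eval item counts per split.
#' @param spec base [phantom_spec()]; each item reuses it with a fresh seed.
#' @param seed master seed.
#' @param m number of frames averaged into the evaluation reference.
#' @return object of class `"phantom_dataset"`.
#' @export
make_dataset <- function(n_train, n_val, n_eval, spec = phantom_spec(),
                         seed = 1, m = 100) {
  stopifnot(is_count(n_train), is_count(n_val), is_count(n_eval))
  if (!is_count(m) || m < 1) stopf("m must be >= 1")
  gen_item <- function(split, i, averaged = FALSE) {
    sp <- spec
    sp$seed <- derive_seed(seed, split, i)
    cl <- make_clean_bscan(sp)
    smp <- corrupt(cl, sp, seed = derive_seed(seed, split, i, 1L))
    if (averaged) {
      acc <- matrix(0, sp$rows, sp$cols)
      for (k in seq_len(m)) {
        s_k <- if (k == 1) smp else
          corrupt(cl, sp, seed = derive_seed(seed, split, i, k))
        acc <- acc + as_pixels(s_k$noisy)
      }
      smp$average <- bscan(acc / m)
      if (is.null(smp$rois)) stopf("evaluation phantom could not host ROIs")
      validate_rois(smp$rois, dim(as_pixels(cl)))
    }
    smp
  }
  ds <- list(
    train = lapply(seq_len(n_train), function(i) gen_item(1L, i)),
    val   = lapply(seq_len(n_val),   function(i) gen_item(2L, i)),
    eval  = lapply(seq_len(n_eval),  function(i) gen_item(3L, i, averaged = TRUE)),
    spec = spec, seed = seed, m = m
  )
  class(ds) <- "phantom_dataset"
  ds
}

#' @export
print.phantom_dataset <- function(x, ...) {
  cat(sprintf("phantom_dataset: %d train / %d val / %d eval (%dx%d, sigma=%g, m=%d)\n",
              length(x$train), length(x$val), length(x$eval),
              x$spec$rows, x$spec$cols, x$spec$noise_sigma, x$m))
  invisible(x)
}
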