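# Structured blind-spot masking with continuous-strip replacement.
#
# A fraction of pixels is sampled as blind-spot centers; each center is
# extended to a 7x1 axial strip (covering the axial noise correlation), and
# the whole strip is overwritten with the *continuous* strip found at a
# random offset within a Chebyshev radius of 5 pixels (offset zero allowed).
# The training loss is evaluated at the center pixels only.

#' Masking configuration
#'
#' @param center_fraction fraction of pixels sampled as blind-spot centers
#'   (0.001 = 0.1%).
#' @param mask_shape `c(axial, lateral)` strip extent; axial must be odd.
#' @param max_offset Chebyshev radius of the replacement source offset.
#' @return object of class `"mask_config"`.
#' @export
mask_config <- function(center_fraction = 0.001, mask_shape = c(7, 1),
                        max_offset = 5) {
  if (center_fraction < 0 || center_fraction > 1)
    stopf("center_fraction must be in [0, 1]")
  if (mask_shape[1] %% 2 == 0 || mask_shape[2] %% 2 == 0)
    stopf("mask_shape extents must be odd")
  if (max_offset < 0) stopf("max_offset must be >= 0")
  structure(list(center_fraction = center_fraction,
                 mask_shape = as.integer(mask_shape),
                 max_offset = as.integer(max_offset)),
            class = "mask_config")
}

#' Sample a mask plan for an image shape
#'
#' Centers are drawn uniformly without replacement from the positions whose
#' strip lies fully inside the image (equivalent to resampling border
#' violations), with count `round(center_fraction * H * W)`. Each center
#' gets one replacement offset drawn uniformly from the
#' `(2 * max_offset + 1)^2` grid, redrawn until the source strip is in
#' bounds. Uses the current RNG stream; seed externally for reproducibility.
#'
#' @param shape image `c(rows, cols)`.
#' @param config a [mask_config()].
#' @return object of class `"mask_plan"` with `centers` (n x 2 matrix),
#'   `offsets` (n x 2, rows `c(d_row, d_col)`), `shape`, `config`, and
#'   `loss_mask` (logical matrix, `TRUE` exactly at centers).
#' @export
build_mask_plan <- function(shape, config = mask_config()) {
  H <- as.integer(shape[1]); W <- as.integer(shape[2])
  ha <- config$mask_shape[1] %/% 2L
  hl <- config$mask_shape[2] %/% 2L
  if (H < config$mask_shape[1] + 2L * config$max_offset ||
      W < config$mask_shape[2] + 2L * config$max_offset)
    stopf("image too small for the mask strip plus max_offset")
  n <- round(config$center_fraction * H * W)
  rows_ok <- (ha + 1L):(H - ha)
  cols_ok <- (hl + 1L):(W - hl)
  if (n > length(rows_ok) * length(cols_ok))
    stopf("center_fraction too large for the valid region")
  pos <- if (n > 0)
    sample.int(length(rows_ok) * length(cols_ok), n, replace = FALSE)
  else integer(0)
  centers <- cbind(rows_ok[((pos - 1L) %% length(rows_ok)) + 1L],
                   cols_ok[((pos - 1L) %/% length(rows_ok)) + 1L])
  offsets <- matrix(0L, n, 2)
  k <- config$max_offset
  for (i in seq_len(n)) {
    repeat {
      d <- c(sample.int(2L * k + 1L, 1L) - k - 1L,
             sample.int(2L * k + 1L, 1L) - k - 1L)
      r <- centers[i, 1] + d[1]; cc <- centers[i, 2] + d[2]
      if (r - ha >= 1 && r + ha <= H && cc - hl >= 1 && cc + hl <= W) {
        offsets[i, ] <- d
        break
      }
    }
  }
  loss_mask <- matrix(FALSE, H, W)
  if (n > 0) loss_mask[centers] <- TRUE
  structure(list(centers = centers, offsets = offsets,
                 shape = c(H, W), config = config, loss_mask = loss_mask),
            class = "mask_plan")
}

# Masked coordinates of one strip (axial x lateral block around a center).
strip_coords <- function(center, mask_shape) {
  ha <- mask_shape[1] %/% 2L; hl <- mask_shape[2] %/% 2L
  as.matrix(expand.grid(row = (center[1] - ha):(center[1] + ha),
                        col = (center[2] - hl):(center[2] + hl)))
}

#' Apply a mask plan to a patch
#'
#' For every center, the whole strip is replaced by the strip at the center's
#' offset; all reads come from the original input, so overlapping strips are
#' resolved in plan order but never chain replacements. Pixels outside all
#' strips are returned bit-identical.
#'
#' @param patch numeric matrix (or [bscan()]) matching the plan's shape.
#' @param plan a [build_mask_plan()] result.
#' @return the masked matrix.
#' @export
apply_mask <- function(patch, plan) {
  x <- as_pixels(patch)
  if (!all(dim(x) == plan$shape)) stopf("plan/patch shape mismatch")
  out <- x
  ha <- plan$config$mask_shape[1] %/% 2L
  hl <- plan$config$mask_shape[2] %/% 2L
  for (i in seq_len(nrow(plan$centers))) {
    r <- plan$centers[i, 1]; cc <- plan$centers[i, 2]
    dr <- plan$offsets[i, 1]; dc <- plan$offsets[i, 2]
    out[(r - ha):(r + ha), (cc - hl):(cc + hl)] <-
      x[(r - ha + dr):(r + ha + dr), (cc - hl + dc):(cc + hl + dc)]
  }
  out
}

#' Serialize / read a mask plan as CSV
#'
#' Columns: `center_row, center_col, d_row, d_col` (1-based centers).
#'
#' @param plan a mask plan.
#' @param path CSV file path.
#' @export
write_mask_plan <- function(plan, path) {
  df <- data.frame(center_row = plan$centers[, 1],
                   center_col = plan$centers[, 2],
                   d_row = plan$offsets[, 1], d_col = plan$offsets[, 2])
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_mask_plan
#' @param shape image shape the plan applies to.
#' @param config the [mask_config()] used when the plan was built.
#' @export
read_mask_plan <- function(path, shape, config = mask_config()) {
  df <- read.csv(path)
  loss_mask <- matrix(FALSE, shape[1], shape[2])
  centers <- cbind(df$center_row, df$center_col)
  if (nrow(df) > 0) loss_mask[centers] <- TRUE
  structure(list(centers = centers, offsets = cbind(df$d_row, df$d_col),
                 shape = shape, config = config, loss_mask = loss_mask),
            class = "mask_plan")
}
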