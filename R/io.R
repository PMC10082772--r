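# File formats: 8-bit PNG/TIFF B-scans, plain-text dataset manifests,
# ROI CSVs, training-history CSVs and model checkpoints.

#' Write / read a B-scan as an 8-bit grayscale image
#'
#' Values are clipped to `[0, 1]` and quantized by round-half-away-from-
#' zero on write; reads return floats in `[0, 1]`. PNG is always
#' available; TIFF requires the `tiff` package.
#'
#' @param image numeric matrix in nominal `[0, 1]`.
#' @param path file path; the extension (`.png` / `.tif(f)`) picks the
#'   format.
#' @return the path (write) or a [bscan()] (read).
#' @export
write_bscan <- function(image, path) {
  x <- to_uint8(as_pixels(image)) / 255
  if (grepl("\\.tiff?$", path, ignore.case = TRUE)) {
    if (!requireNamespace("tiff", quietly = TRUE))
      stopf("the tiff package is required for TIFF output")
    tiff::writeTIFF(x, path, bits.per.sample = 8L)
  } else {
    png::writePNG(x, path)
  }
  invisible(path)
}

#' @rdname write_bscan
#' @export
read_bscan <- function(path) {
  x <- if (grepl("\\.tiff?$", path, ignore.case = TRUE)) {
    if (!requireNamespace("tiff", quietly = TRUE))
      stopf("the tiff package is required for TIFF input")
    tiff::readTIFF(path)
  } else {
    png::readPNG(path)
  }
  if (length(dim(x)) == 3) x <- x[, , 1]
  bscan(x)
}

#' Serialize an ROI set as CSV
#'
#' Columns `label, row0, row1, col0, col1`, 0-based half-open intervals;
#' `label` is `"background"` or `"fg<i>"`.
#'
#' @param rois a `"roi_set"`.
#' @param path CSV path.
#' @export
write_rois <- function(rois, path) {
  to_row <- function(label, r)
    data.frame(label = label, row0 = r[1] - 1L, row1 = r[2],
               col0 = r[3] - 1L, col1 = r[4])
  df <- do.call(rbind, c(list(to_row("background", rois$background)),
                         lapply(seq_along(rois$foreground), function(i)
                           to_row(sprintf("fg%02d", i), rois$foreground[[i]]))))
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_rois
#' @export
read_rois <- function(path) {
  df <- read.csv(path)
  from_row <- function(r) c(r$row0 + 1L, r$row1, r$col0 + 1L, r$col1)
  bg <- df[df$label == "background", ]
  fg <- df[df$label != "background", ]
  structure(list(foreground = lapply(seq_len(nrow(fg)),
                                     function(i) from_row(fg[i, ])),
                 background = from_row(bg[1, ])),
            class = "roi_set")
}

# manifest: plain-text "key = value" lines
write_manifest <- function(values, path) {
  lines <- vapply(names(values), function(k)
    sprintf("%s = %s", k, paste(format(values[[k]], digits = 12),
                                collapse = " ")), character(1))
  writeLines(lines, path)
  invisible(path)
}

read_manifest <- function(path) {
  lines <- readLines(path)
  out <- list()
  for (ln in lines) {
    kv <- strsplit(ln, " = ", fixed = TRUE)[[1]]
    vals <- strsplit(kv[2], " ", fixed = TRUE)[[1]]
    num <- suppressWarnings(as.numeric(vals))
    out[[kv[1]]] <- if (!anyNA(num)) num else vals
  }
  out
}

#' Write a phantom dataset to a directory
#'
#' Per-image 8-bit PNGs (noisy, clean, and for evaluation items the
#' averaged reference), per-item ROI CSVs, and a plain-text manifest with
#' the generator spec and seeds.
#'
#' @param ds a `"phantom_dataset"`.
#' @param dir output directory (created if missing).
#' @export
write_dataset <- function(ds, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (split in c("train", "val", "eval")) {
    items <- ds[[split]]
    for (i in seq_along(items)) {
      stem <- file.path(dir, sprintf("%s_%03d", split, i))
      write_bscan(items[[i]]$noisy, paste0(stem, "_noisy.png"))
      write_bscan(items[[i]]$clean, paste0(stem, "_clean.png"))
      if (!is.null(items[[i]]$average))
        write_bscan(items[[i]]$average, paste0(stem, "_avg.png"))
      if (!is.null(items[[i]]$rois))
        write_rois(items[[i]]$rois, paste0(stem, "_rois.csv"))
    }
  }
  sp <- ds$spec
  write_manifest(list(
    rows = sp$rows, cols = sp$cols, n_layers = sp$n_layers,
    reflectivities = sp$reflectivities, floor = sp$floor,
    amp_frac = sp$amp_frac, n_harmonics = sp$n_harmonics,
    membrane = as.integer(sp$membrane), noise_sigma = sp$noise_sigma,
    sigma_ax = sp$sigma_ax, sigma_lat = sp$sigma_lat,
    seed = ds$seed, m = ds$m,
    n_train = length(ds$train), n_val = length(ds$val),
    n_eval = length(ds$eval),
    package_version = as.character(utils::packageVersion("blindspot"))),
    file.path(dir, "manifest.txt"))
  invisible(dir)
}

#' Read back a phantom dataset directory
#'
#' Images come back as `[0, 1]` floats (8-bit quantized); the manifest is
#' attached as the `spec` summary.
#'
#' @param dir dataset directory written by [write_dataset()].
#' @return list with `train` / `val` / `eval` splits and `manifest`.
#' @export
read_dataset <- function(dir) {
  man <- read_manifest(file.path(dir, "manifest.txt"))
  rd <- function(split, n) lapply(seq_len(n), function(i) {
    stem <- file.path(dir, sprintf("%s_%03d", split, i))
    item <- list(noisy = read_bscan(paste0(stem, "_noisy.png")),
                 clean = read_bscan(paste0(stem, "_clean.png")))
    if (file.exists(paste0(stem, "_avg.png")))
      item$average <- read_bscan(paste0(stem, "_avg.png"))
    if (file.exists(paste0(stem, "_rois.csv")))
      item$rois <- read_rois(paste0(stem, "_rois.csv"))
    class(item) <- "phantom_sample"
    item
  })
  list(train = rd("train", man$n_train), val = rd("val", man$n_val),
       eval = rd("eval", man$n_eval), manifest = man)
}

#' Save / load a trained model checkpoint
#'
#' One container file holding the architecture spec, weights,
#' normalization statistics, training configuration and history.
#'
#' @param fit a `"blindspot"` fit.
#' @param path checkpoint path (`.rds`).
#' @export
save_checkpoint <- function(fit, path) {
  saveRDS(fit, path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  fit <- readRDS(path)
  if (!inherits(fit, "blindspot")) stopf("not a blindspot checkpoint")
  fit
}

#' Export training history as CSV
#'
#' Columns `epoch, train_loss, val_loss, lr`.
#'
#' @param fit a `"blindspot"` fit.
#' @param path CSV path.
#' @export
write_history <- function(fit, path) {
  write.csv(fit$history, path, row.names = FALSE)
  invisible(path)
}
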