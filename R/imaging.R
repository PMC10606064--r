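#' Otsu threshold of an intensity raster
#'
#' Exhaustive search over the boundaries of a 256-bin histogram (computed
#' on min-max-scaled intensities, matching 8-bit image-analysis practice)
#' for the threshold minimising the intra-class variance — the weighted sum
#' of the variances of the two classes.  Deterministic; ties resolve to the
#' lowest qualifying threshold.
#'
#' @param raster Numeric matrix or vector with at least 2 distinct values.
#' @param n_bins Histogram bins (default 256).
#' @return A scalar threshold on the original intensity scale; foreground
#'   is `raster > threshold`.
#' @export
otsu_threshold <- function(raster, n_bins = 256) {
  x <- as.numeric(raster)
  x <- x[is.finite(x)]
  rng <- range(x)
  if (diff(rng) == 0) abort("constant image: Otsu threshold undefined.")
  # bin index 1..n_bins on the min-max scaled intensities; per-bin moment
  # sums keep the intra-class variances exact (no midpoint approximation)
  idx <- pmin(n_bins, 1L + floor((x - rng[1L]) / diff(rng) * n_bins))
  counts <- tabulate(idx, nbins = n_bins)
  sx <- sxx <- numeric(n_bins)
  mom <- rowsum(cbind(x, x^2), idx)
  bins <- as.integer(rownames(mom))
  sx[bins] <- mom[, 1L]
  sxx[bins] <- mom[, 2L]

  n <- length(x)
  w0 <- cumsum(counts)                       # pixels in class <= k
  s0 <- cumsum(sx)
  q0 <- cumsum(sxx)
  w1 <- n - w0
  # candidate thresholds after bin k, for k with both classes non-empty
  valid <- which(w0 > 0 & w1 > 0)
  if (!length(valid)) abort("constant image: Otsu threshold undefined.")
  mu0 <- s0[valid] / w0[valid]
  mu1 <- (s0[n_bins] - s0[valid]) / w1[valid]
  var0 <- q0[valid] / w0[valid] - mu0^2
  var1 <- (q0[n_bins] - q0[valid]) / w1[valid] - mu1^2
  within <- (w0[valid] * var0 + w1[valid] * var1) / n
  k <- valid[which.min(within)]
  # cut in the middle of the intensity gap between the two classes, so
  # `raster > threshold` reproduces the optimal split exactly
  (max(x[idx <= k]) + min(x[idx > k])) / 2
}

#' Segment the cell from the actin channel
#'
#' Otsu binarisation of the actin (cell outline) channel, hole filling,
#' and retention of the largest connected component: the single-cell
#' contract of the surface-fraction measurement.
#'
#' @param actin_channel Numeric matrix.
#' @return A logical matrix cell mask with positive area.
#' @export
cell_mask <- function(actin_channel) {
  thr <- otsu_threshold(actin_channel)
  bw <- actin_channel > thr
  if (!any(bw)) abort("empty foreground: no cell detected in the actin channel.")
  filled <- EBImage::fillHull(EBImage::Image(bw * 1))
  lab <- EBImage::bwlabel(filled)
  labs <- as.integer(lab)
  labs <- labs[labs > 0]
  biggest <- as.integer(names(which.max(table(labs))))
  mask <- matrix(as.integer(lab) == biggest,
                 nrow = nrow(actin_channel), ncol = ncol(actin_channel))
  if (!any(mask)) abort("empty cell mask.")
  mask
}

#' Microtubule surface fraction of a single cell
#'
#' The cell mask comes from the actin channel ([cell_mask()]); the
#' microtubule mask is an Otsu binarisation of the tubulin channel with
#' the threshold computed over the cell pixels only; the readout is
#' `100 * mt_area / cell_area`, the percent of the cell surface occupied
#' by the microtubule network.
#'
#' @param tubulin_channel,actin_channel Numeric matrices of equal
#'   dimensions; a `tau_cell_image` from [simulate_cell_image()] may be
#'   given as the first argument instead.
#' @param background_offset Optional constant subtracted from the tubulin
#'   channel before thresholding (default 0: no background subtraction).
#' @param local,local_radius Use a local (circular-ROI) Otsu threshold of
#'   the given pixel radius instead of the global one.  The local variant
#'   is O(pixels x radius^2) and intended for small crops.
#' @return A one-row tibble: `cell_area_px`, `mt_area_px`, `ratio_pct`.
#' @examples
#' truth <- image_truth(width = 96, height = 96, mt_coverage_of_cell = 0.39,
#'                      seed = 7)
#' img <- simulate_cell_image(truth)
#' microtubule_surface_ratio(img)
#' @export
microtubule_surface_ratio <- function(tubulin_channel, actin_channel = NULL,
                                      background_offset = 0,
                                      local = FALSE, local_radius = 15) {
  if (inherits(tubulin_channel, "tau_cell_image")) {
    img <- tubulin_channel
    actin_channel <- img$actin
    tubulin_channel <- img$tubulin
  }
  if (is.null(actin_channel)) abort("an actin channel is required.")
  if (!all(dim(tubulin_channel) == dim(actin_channel))) {
    abort("channel dimensions differ.")
  }
  mask <- cell_mask(actin_channel)
  tub <- tubulin_channel - background_offset
  inside <- tub[mask]
  if (length(unique(inside)) < 2) {
    # no contrast inside the cell: decide saturated vs empty against the
    # whole-channel threshold (uniformly bright cell interior = full
    # coverage; uniformly dark = none)
    mt_area <- if (length(unique(as.numeric(tub))) < 2) {
      0L
    } else {
      sum(inside > otsu_threshold(tub))
    }
  } else if (local) {
    thr_map <- local_otsu_map(tub, mask, local_radius)
    mt_area <- sum(inside > thr_map[mask])
  } else {
    thr <- otsu_threshold(inside)
    mt_area <- sum(inside > thr)
  }
  cell_area <- sum(mask)
  tibble::tibble(cell_area_px = cell_area, mt_area_px = as.integer(mt_area),
                 ratio_pct = 100 * mt_area / cell_area)
}

# Per-pixel Otsu threshold over a circular neighbourhood, computed only at
# mask pixels.  Quadratic in radius per pixel; meant for small crops.
local_otsu_map <- function(raster, mask, radius) {
  h <- nrow(raster); w <- ncol(raster)
  thr <- matrix(NA_real_, h, w)
  off <- expand.grid(dr = -radius:radius, dc = -radius:radius)
  off <- off[off$dr^2 + off$dc^2 <= radius^2, ]
  global_thr <- otsu_threshold(raster)
  idx <- which(mask, arr.ind = TRUE)
  for (i in seq_len(nrow(idx))) {
    r <- idx[i, 1L]; c <- idx[i, 2L]
    rr <- r + off$dr; cc <- c + off$dc
    ok <- rr >= 1 & rr <= h & cc >= 1 & cc <= w
    vals <- raster[cbind(rr[ok], cc[ok])]
    # a contrast-free neighbourhood falls back to the global threshold
    thr[r, c] <- if (diff(range(vals)) == 0) global_thr else otsu_threshold(vals)
  }
  thr
}

#' Write / read a two-channel cell image as TIFF
#'
#' Channels are written as a two-slice 32-bit float TIFF (tubulin first),
#' intensities rescaled to [0, 1] by the stored `scale`.
#'
#' @param img A `tau_cell_image` or a list with matrices `tubulin`,
#'   `actin`.
#' @param path Output path.
#' @return `write_cell_image_tiff()` returns `path` invisibly;
#'   `read_cell_image_tiff()` returns a list with `tubulin` and `actin`
#'   matrices on the stored scale.
#' @export
write_cell_image_tiff <- function(img, path) {
  scale <- max(img$tubulin, img$actin, 1)
  arr <- list(img$tubulin / scale, img$actin / scale)
  tiff::writeTIFF(arr, path, bits.per.sample = 32L)
  invisible(path)
}

#' @rdname write_cell_image_tiff
#' @param scale Intensity scale to restore on read (default 1).
#' @export
read_cell_image_tiff <- function(path, scale = 1) {
  sl <- tiff::readTIFF(path, all = TRUE)
  if (length(sl) < 2) abort("expected a two-channel (two-slice) TIFF.")
  list(tubulin = sl[[1L]] * scale, actin = sl[[2L]] * scale)
}

#' Sidecar files for a synthetic cell image
#'
#' Writes the ground-truth masks as 1-bit-style PNGs and the generator
#' truth as JSON next to an image, so recovery tests can reload the exact
#' conditions a dataset was produced under.
#'
#' @param img A `tau_cell_image`.
#' @param dir Output directory (created if needed).
#' @param prefix File-name prefix.
#' @return The directory, invisibly; files `<prefix>_cell_mask.png`,
#'   `<prefix>_mt_mask.png`, `<prefix>_truth.json`.
#' @export
write_image_sidecars <- function(img, dir, prefix = "cell") {
  stopifnot(inherits(img, "tau_cell_image"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  png::writePNG(img$cell_mask * 1,
                file.path(dir, paste0(prefix, "_cell_mask.png")))
  png::writePNG(img$mt_mask * 1,
                file.path(dir, paste0(prefix, "_mt_mask.png")))
  jsonlite::write_json(unclass(img$truth),
                       file.path(dir, paste0(prefix, "_truth.json")),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @export
print.tau_cell_image <- function(x, ...) {
  cat(sprintf(
    "<tau_cell_image> %d x %d px; cell %d px (%.1f%% of frame); mt coverage %.1f%% of cell\n",
    x$truth$width, x$truth$height, sum(x$cell_mask),
    100 * mean(x$cell_mask), 100 * sum(x$mt_mask) / sum(x$cell_mask)))
  invisible(x)
}
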