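#' 8-bit RGB image container with physical scale
#'
#' @param pixels H x W x 3 numeric array with values in \[0, 255\].
#' @param um_per_px Micrometers per pixel (> 0).
#' @return An `rgb_image`.
#' @export
rgb_image <- function(pixels, um_per_px) {
  if (length(dim(pixels)) != 3L || dim(pixels)[3] != 3L)
    stop("pixels must be an H x W x 3 array")
  if (um_per_px <= 0) stop("um_per_px must be positive")
  if (min(pixels) < 0 || max(pixels) > 255)
    stop("pixel values must lie in [0, 255]")
  structure(list(pixels = pixels, um_per_px = um_per_px), class = "rgb_image")
}

#' @export
print.rgb_image <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("rgb_image: %d x %d px (%.3g um/px)\n", d[1], d[2], x$um_per_px))
  invisible(x)
}

#' Read / write an RGB image as PNG with a JSON scale sidecar
#'
#' The µm-per-pixel scale travels in `<path>.json` next to the image.
#'
#' @param path PNG path.
#' @param um_per_px Scale override; when NULL the sidecar is required.
#' @return An `rgb_image`.
#' @export
read_rgb_image <- function(path, um_per_px = NULL) {
  px <- png::readPNG(path)
  if (length(dim(px)) == 2L) px <- array(rep(px, 3), dim = c(dim(px), 3))
  px <- round(px[, , 1:3, drop = FALSE] * 255)
  if (is.null(um_per_px)) {
    sidecar <- paste0(path, ".json")
    if (!file.exists(sidecar)) stop("no um_per_px given and no sidecar found")
    um_per_px <- jsonlite::read_json(sidecar)$um_per_px
  }
  rgb_image(px, um_per_px)
}

#' @rdname read_rgb_image
#' @param img An `rgb_image`.
#' @export
write_rgb_image <- function(img, path) {
  png::writePNG(img$pixels / 255, path)
  jsonlite::write_json(list(um_per_px = img$um_per_px), paste0(path, ".json"),
                       auto_unbox = TRUE)
  invisible(path)
}

#' Clear near-black artifacts
#'
#' Pixels with all three channels below `black_threshold` are replaced by
#' background white (255, 255, 255), so they fall into the extreme
#' histogram bin ignored by the auto-threshold.
#'
#' @param img An `rgb_image`.
#' @param black_threshold 8-bit cutoff (default 30; 0 disables clearing).
#' @return The cleared `rgb_image`.
#' @export
clear_artifacts <- function(img, black_threshold = 30) {
  stopifnot(inherits(img, "rgb_image"))
  px <- img$pixels
  black <- px[, , 1] < black_threshold & px[, , 2] < black_threshold &
    px[, , 3] < black_threshold
  for (ch in 1:3) {
    plane <- px[, , ch]
    plane[black] <- 255
    px[, , ch] <- plane
  }
  rgb_image(px, img$um_per_px)
}

# 256-bin histogram of an 8-bit channel matrix.
channel_histogram <- function(channel) {
  tabulate(as.integer(channel) + 1L, nbins = 256L)
}

#' Isodata (intermeans) auto-threshold
#'
#' Iterative intermeans on a 256-bin histogram: starting from the lowest
#' occupied bin, the candidate threshold t advances until t + 1 exceeds the
#' average of the mean intensity below (<= t) and above (> t); the rounded
#' fixed point is returned. Following the ImageJ "Default" behavior, the
#' extreme bins (0 and 255) are ignored so cleared/erased areas do not
#' enter the threshold.
#'
#' @param histogram Integer vector of 256 bin counts (values 0-255).
#' @param ignore_extremes Zero out bins 0 and 255 before thresholding
#'   (default TRUE).
#' @return Integer threshold in 0-255.
#' @export
isodata_threshold <- function(histogram, ignore_extremes = TRUE) {
  h <- as.numeric(histogram)
  if (length(h) != 256L) stop("histogram must have 256 bins")
  if (sum(h) == 0) stop("empty histogram")
  if (ignore_extremes) {
    h2 <- h
    h2[c(1L, 256L)] <- 0
    if (sum(h2) > 0) h <- h2
  }
  vals <- 0:255
  occupied <- which(h > 0)
  lo <- min(occupied) - 1L  # bin values, 0-based
  hi <- max(occupied) - 1L
  if (lo == hi) {
    warning("single-valued histogram; returning that value")
    return(lo)
  }
  for (t in lo:(hi - 1L)) {
    below <- h[(lo:t) + 1L]
    above <- h[((t + 1L):hi) + 1L]
    mb <- sum((lo:t) * below) / sum(below)
    ma <- sum(((t + 1L):hi) * above) / sum(above)
    result <- (mb + ma) / 2
    if (t + 1 > result) return(as.integer(round(result)))
  }
  as.integer(round((lo + hi) / 2))
}

#' Tissue mask from the blue channel
#'
#' Auto-thresholds the blue-channel histogram with [isodata_threshold()];
#' tissue is darker than the near-white background, so tissue pixels are
#' those with blue value at or below the threshold.
#'
#' @param img A cleared `rgb_image`.
#' @param invert Flip the polarity (tissue = above threshold).
#' @return Logical H x W matrix, with the threshold in the `"threshold"`
#'   attribute.
#' @export
tissue_mask <- function(img, invert = FALSE) {
  stopifnot(inherits(img, "rgb_image"))
  blue <- img$pixels[, , 3]
  t <- isodata_threshold(channel_histogram(blue))
  mask <- if (all(blue == blue[1])) {
    # degenerate flat channel: dark means all tissue, bright means none
    matrix(blue[1] < 128, nrow(blue), ncol(blue))
  } else if (invert) blue > t else blue <= t
  attr(mask, "threshold") <- t
  mask
}

#' Stain mask from the green channel with a brightness factor
#'
#' Sirius red suppresses the green channel, so stained pixels are those
#' with green value at or below the effective threshold. The effective
#' threshold is the isodata auto-threshold of the green histogram divided
#' by the experiment-specific brightness factor (typically 0.95 or 1.3),
#' making the stained area monotone non-increasing in the factor.
#'
#' @param img A cleared `rgb_image`.
#' @param brightness_factor Positive divisor applied to the threshold
#'   (default 1).
#' @param invert Flip the polarity.
#' @return Logical H x W matrix with `"threshold"` (base) and
#'   `"effective_threshold"` attributes.
#' @export
stain_mask <- function(img, brightness_factor = 1.0, invert = FALSE) {
  stopifnot(inherits(img, "rgb_image"))
  if (brightness_factor <= 0) stop("brightness_factor must be positive")
  green <- img$pixels[, , 2]
  t <- isodata_threshold(channel_histogram(green))
  eff <- t / brightness_factor
  mask <- if (all(green == green[1])) {
    matrix(green[1] < 128, nrow(green), ncol(green))
  } else if (invert) green > eff else green <= eff
  attr(mask, "threshold") <- t
  attr(mask, "effective_threshold") <- eff
  mask
}

#' Square regions of interest around organoids
#'
#' @param centers Data.frame with `cx`, `cy` pixel centers (optionally an
#'   `image` id column).
#' @param side_um Side length in micrometers (default 200).
#' @return A `roi_spec` data.frame.
#' @export
roi_spec <- function(centers, side_um = 200) {
  stopifnot(all(c("cx", "cy") %in% colnames(centers)))
  centers$side_um <- side_um
  class(centers) <- c("roi_spec", "data.frame")
  centers
}

# Clip one ROI square to the image bounds; returns row/col index ranges.
roi_bounds <- function(img, cx, cy, side_um) {
  d <- dim(img$pixels)
  side_px <- round(side_um / img$um_per_px)
  half <- side_px / 2
  r0 <- max(1L, round(cy - half)); r1 <- min(d[1], round(cy + half) - 1L)
  c0 <- max(1L, round(cx - half)); c1 <- min(d[2], round(cx + half) - 1L)
  if (r0 > r1 || c0 > c1) stop("ROI fully outside the image")
  list(rows = r0:r1, cols = c0:c1)
}

#' Quantify stained and tissue area per region
#'
#' Computes, for the whole image or for each 200 x 200 µm ROI: region,
#' tissue and stained pixel counts (stain counted inside tissue),
#' percentage stained per total area, percentage stained per tissue
#' (flagged undefined when the region holds no tissue), and the stain-free
#' share of the region (non-tissue pixels; the tissue-rarefaction/vacuole
#' readout).
#'
#' @param img An `rgb_image` (artifacts are cleared internally).
#' @param rois Optional [roi_spec()]; NULL quantifies the whole image.
#' @param brightness_factor Passed to [stain_mask()].
#' @param black_threshold Passed to [clear_artifacts()].
#' @param stain_free_within_tissue Report the stain-free percentage as the
#'   unstained share of the tissue mask instead of the non-tissue share of
#'   the region (default FALSE).
#' @return Data.frame (class `stain_quant`) with one row per region.
#' @export
quantify <- function(img, rois = NULL, brightness_factor = 1.0,
                     black_threshold = 30,
                     stain_free_within_tissue = FALSE) {
  stopifnot(inherits(img, "rgb_image"))
  cleared <- clear_artifacts(img, black_threshold)
  tis <- tissue_mask(cleared)
  stn <- stain_mask(cleared, brightness_factor) & tis
  regions <- if (is.null(rois)) {
    d <- dim(img$pixels)
    list(list(id = "whole_image", rows = seq_len(d[1]), cols = seq_len(d[2])))
  } else {
    lapply(seq_len(nrow(rois)), function(i) {
      b <- roi_bounds(img, rois$cx[i], rois$cy[i], rois$side_um[i])
      c(list(id = sprintf("roi%02d", i)), b)
    })
  }
  rows <- lapply(regions, function(rg) {
    tsub <- tis[rg$rows, rg$cols]
    ssub <- stn[rg$rows, rg$cols]
    region_px <- length(tsub)
    tissue_px <- sum(tsub)
    stained_px <- sum(ssub)
    data.frame(
      region = rg$id, region_px = region_px, tissue_px = tissue_px,
      stained_px = stained_px,
      pct_stained_per_area = 100 * stained_px / region_px,
      pct_stained_per_tissue = if (tissue_px > 0)
        100 * stained_px / tissue_px else 0,
      tissue_empty = tissue_px == 0,
      pct_stain_free = if (stain_free_within_tissue) {
        if (tissue_px > 0) 100 * (tissue_px - stained_px) / tissue_px else 0
      } else 100 * (region_px - tissue_px) / region_px,
      brightness_factor = brightness_factor,
      tissue_threshold = attr(tis, "threshold"),
      stain_threshold = attr(stain_mask(cleared, brightness_factor),
                             "effective_threshold"),
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("stain_quant", "data.frame")
  out
}

#' Normalize measurements to the control mean
#'
#' Each value is divided by the mean of the control values (times 100 when
#' `percent` is requested), so the control group's normalized mean is 1
#' (or 100). Used both for stain percentages and for contraction-assay
#' areas.
#'
#' @param values Numeric vector.
#' @param control Logical mask or indices of the control entries.
#' @param percent Return percentages of the control mean.
#' @return Normalized numeric vector.
#' @export
normalize_to_control <- function(values, control, percent = FALSE) {
  ctrl <- values[control]
  if (!length(ctrl)) stop("need at least one control value")
  m <- mean(ctrl)
  if (m == 0) stop("control mean is zero")
  values / m * if (percent) 100 else 1
}
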