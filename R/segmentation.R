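#' Calibrated grayscale image
#'
#' Wraps a 2D intensity matrix together with its physical scale. All
#' downstream measurements are carried out in pixels and converted to
#' micrometres through `scale` exactly once.
#'
#' @param pixels Numeric matrix of intensities, indexed `[y, x]`.
#' @param scale Physical length of one pixel in micrometres per pixel
#'   (must be > 0).
#' @return An object of class `calibrated_image`: the intensity matrix
#'   with attributes `scale`.
#' @export
calibrated_image <- function(pixels, scale = 1) {
  pixels <- as.matrix(pixels)
  if (nrow(pixels) < 1L || ncol(pixels) < 1L)
    stop("image must have at least one row and one column")
  if (!all(is.finite(pixels)))
    stop("image intensities must be finite")
  if (!is.numeric(scale) || length(scale) != 1L || !is.finite(scale) || scale <= 0)
    stop("`scale` must be a single positive number (um per pixel)")
  structure(pixels, scale = scale, class = c("calibrated_image", "matrix"))
}

#' @export
print.calibrated_image <- function(x, ...) {
  cat(sprintf("calibrated_image: %d x %d px, %.4g um/px, intensity range [%.4g, %.4g]\n",
              ncol(x), nrow(x), attr(x, "scale"), min(x), max(x)))
  invisible(x)
}

#' Read a PNG or TIFF micrograph as a calibrated image
#'
#' Multi-channel rasters are reduced to luminance via [to_grayscale()].
#'
#' @param path Path to an 8/16-bit PNG or TIFF file.
#' @inheritParams calibrated_image
#' @return A [calibrated_image()].
#' @export
read_micrograph <- function(path, scale = 1) {
  if (!file.exists(path)) stop("cannot read image: ", path)
  ext <- tolower(tools::file_ext(path))
  raw <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path),
    stop("unsupported image format: .", ext, " (use PNG or TIFF)"))
  to_grayscale(raw, scale = scale)
}

#' Convert a multi-channel raster to calibrated grayscale
#'
#' Single-channel inputs pass through unchanged. RGB channels are combined
#' with the ITU-R BT.601 luminance weights (0.299, 0.587, 0.114); an alpha
#' channel, if present, is ignored.
#'
#' @param image A 2D matrix (already grayscale) or a 3D array `[y, x, c]`
#'   with 1--4 channels.
#' @inheritParams calibrated_image
#' @return A [calibrated_image()].
#' @export
to_grayscale <- function(image, scale = 1) {
  if (is.matrix(image) || length(dim(image)) == 2L)
    return(calibrated_image(as.matrix(image), scale))
  d <- dim(image)
  if (length(d) != 3L || d[3] < 1L || d[3] > 4L)
    stop("expected a 2D matrix or a 3D array with 1-4 channels")
  if (d[1] < 1L || d[2] < 1L) stop("image must have at least one row and one column")
  g <- switch(as.character(d[3]),
    "1" = image[, , 1],
    "2" = image[, , 1],                       # gray + alpha
    image[, , 1] * 0.299 + image[, , 2] * 0.587 + image[, , 3] * 0.114)
  calibrated_image(g, scale)
}

#' FFT band-pass pre-filter
#'
#' Suppresses low-frequency shading (features larger than `large_cut`
#' pixels) and high-frequency noise (features smaller than `small_cut`
#' pixels) by multiplying the Fourier spectrum with a Gaussian band-pass
#' transfer function, evening out brightness across the micrograph before
#' thresholding. The DC component is removed, so the output has zero mean.
#'
#' The transfer function at radial frequency f (cycles/px) is
#' `exp(-2 (f * small_cut)^2) * (1 - exp(-2 (f * large_cut)^2))`:
#' a feature of characteristic size d px lives near f = 1/d, so sizes well
#' inside (`small_cut`, `large_cut`) pass nearly unattenuated. Non-even
#' dimensions are mirror-padded by one pixel for the transform and cropped
#' back, avoiding wrap-around bias at the frame.
#'
#' Features of interest should span at least 12--15 px for reliable
#' downstream measurement; a `small_cut` near or above the feature size is
#' warned about.
#'
#' @param image A [calibrated_image()].
#' @param small_cut Smallest feature size kept, px. Default 3.
#' @param large_cut Largest feature size kept, px. Default 40% of the
#'   smaller image dimension.
#' @return A [calibrated_image()] of the filtered intensities (zero-mean).
#' @export
fft_bandpass <- function(image, small_cut = 3, large_cut = NULL) {
  stopifnot(inherits(image, "calibrated_image"))
  H <- nrow(image); W <- ncol(image)
  if (is.null(large_cut)) large_cut <- max(4, round(0.4 * min(H, W)))
  if (!(small_cut > 0 && small_cut < large_cut))
    stop("need 0 < small_cut < large_cut")
  if (large_cut > max(H, W))
    stop("large_cut exceeds the image dimensions")
  if (small_cut >= 12)
    warning("small_cut >= 12 px: features of interest near the 12-15 px reliability floor will be attenuated")

  m <- unclass(image)[, , drop = FALSE]
  m <- matrix(as.numeric(m), H, W)
  # mirror-pad odd dimensions to even size
  if (H %% 2L == 1L) m <- rbind(m, m[H, , drop = FALSE])
  if (W %% 2L == 1L) m <- cbind(m, m[, ncol(m), drop = FALSE])
  Hp <- nrow(m); Wp <- ncol(m)

  fy <- c(0:(Hp / 2), seq(-(Hp / 2 - 1), -1)) / Hp
  fx <- c(0:(Wp / 2), seq(-(Wp / 2 - 1), -1)) / Wp
  f2 <- outer(fy^2, fx^2, `+`)
  transfer <- exp(-2 * f2 * small_cut^2) * (1 - exp(-2 * f2 * large_cut^2))

  out <- Re(fft(fft(m) * transfer, inverse = TRUE)) / (Hp * Wp)
  out <- out[seq_len(H), seq_len(W), drop = FALSE]
  calibrated_image(out, attr(image, "scale"))
}

#' Binarise a calibrated image at a manual threshold
#'
#' Thresholding is deliberately manual: the satisfactory value depends on
#' imaging modality and material and is chosen by inspection (an Otsu
#' starting point is available via [suggest_threshold()], and its use is
#' recorded in the mask's provenance). By default dark pixels are pore
#' (backscatter SEM convention); set `invert = TRUE` when pores image
#' bright (e.g. micro-CT of low-density scaffolds).
#'
#' @param image A [calibrated_image()].
#' @param threshold Intensity cut. With `invert = FALSE` a pixel is pore
#'   iff intensity <= threshold.
#' @param invert If TRUE, bright pixels (> threshold) are pore.
#' @param provenance Free-form note on how the threshold was chosen
#'   (default "manual"); recorded on the mask.
#' @return A `binary_mask`: logical matrix (TRUE = pore) with attributes
#'   `scale`, `threshold`, `invert`, `provenance`.
#' @export
binarize <- function(image, threshold, invert = FALSE, provenance = "manual") {
  stopifnot(inherits(image, "calibrated_image"))
  if (!is.finite(threshold)) stop("threshold must be finite")
  m <- matrix(as.numeric(unclass(image)), nrow(image), ncol(image))
  lab <- if (invert) m > threshold else m <= threshold
  binary_mask(lab, scale = attr(image, "scale"), threshold = threshold,
              invert = invert, provenance = provenance)
}

#' Construct a binary pore mask
#'
#' @param labels Logical matrix, TRUE = pore/void, FALSE = solid.
#' @param scale Micrometres per pixel.
#' @param threshold,invert,provenance Provenance of the binarisation;
#'   free-form for pre-binarised masks.
#' @return An object of class `binary_mask`.
#' @export
binary_mask <- function(labels, scale = 1, threshold = NA_real_,
                        invert = FALSE, provenance = "external") {
  labels <- as.matrix(labels)
  if (!is.logical(labels)) {
    labels <- labels > max(labels) / 2  # 0/255 or 0/1 rasters
  }
  if (nrow(labels) < 1L || ncol(labels) < 1L) stop("mask must be non-empty")
  if (!is.numeric(scale) || scale <= 0) stop("`scale` must be positive")
  structure(labels, scale = scale, threshold = threshold, invert = invert,
            provenance = provenance, class = c("binary_mask", "matrix"))
}

#' @export
print.binary_mask <- function(x, ...) {
  cat(sprintf("binary_mask: %d x %d px, %.4g um/px, porosity %.4f (threshold %s, %s)\n",
              ncol(x), nrow(x), attr(x, "scale"), mean(x),
              format(attr(x, "threshold")), attr(x, "provenance")))
  invisible(x)
}

#' Read a pre-binarised mask from a PNG (0/255 or 0/1)
#'
#' @inheritParams read_micrograph
#' @export
read_mask <- function(path, scale = 1) {
  img <- read_micrograph(path, scale = scale)
  binary_mask(unclass(img) > 0.5, scale = scale, provenance = paste0("file:", basename(path)))
}

#' Write a binary mask to PNG (pore = white)
#'
#' @param mask A `binary_mask`.
#' @param path Output PNG path.
#' @export
write_mask <- function(mask, path) {
  png::writePNG(matrix(as.numeric(mask), nrow(mask), ncol(mask)), path)
  invisible(path)
}

#' Otsu threshold suggestion
#'
#' Convenience starting point for manual threshold selection; never
#' applied automatically. Maximises between-class variance on a 256-bin
#' histogram of the intensity range.
#'
#' @param image A [calibrated_image()].
#' @return A single threshold on the image's intensity scale.
#' @export
suggest_threshold <- function(image) {
  v <- as.numeric(unclass(image))
  rng <- range(v)
  if (diff(rng) == 0) return(rng[1])
  brk <- seq(rng[1], rng[2], length.out = 257L)
  h <- tabulate(findInterval(v, brk, rightmost.closed = TRUE), nbins = 256L)
  p <- h / sum(h)
  mids <- (brk[-1] + brk[-257]) / 2
  w0 <- cumsum(p)
  mu <- cumsum(p * mids)
  mu_t <- mu[256]
  between <- (mu_t * w0 - mu)^2 / (w0 * (1 - w0))
  between[!is.finite(between)] <- 0
  # the criterion is flat across an empty gap between modes; take the
  # middle of the maximising plateau rather than its first bin
  best <- which(between >= max(between) - 1e-12)
  mids[best[ceiling(length(best) / 2)]]
}
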