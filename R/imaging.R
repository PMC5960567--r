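#' Radiograph constructor
#'
#' A real radiograph (DR): an intensity raster in [0, 1] with its physical
#' pixel spacing. Binary radiographs (prosthesis segmentations) carry
#' `is_binary = TRUE` and contain only 0/1.
#'
#' @param intensity numeric matrix, values in [0, 1] (rows = image y).
#' @param pixel_spacing mm/px.
#' @param is_binary logical; if `TRUE` values must be exactly 0 or 1.
#' @return object of class `radiograph`.
#' @export
radiograph <- function(intensity, pixel_spacing, is_binary = NULL) {
  intensity <- as.matrix(intensity)
  if (anyNA(intensity) || min(intensity) < 0 || max(intensity) > 1)
    stop("radiograph intensities must lie in [0, 1]")
  if (is.null(is_binary)) is_binary <- all(intensity %in% c(0, 1))
  if (is_binary && !all(intensity %in% c(0, 1)))
    stop("binary radiograph must contain only 0/1 values")
  structure(list(intensity = intensity,
                 pixel_spacing = as.numeric(pixel_spacing),
                 is_binary = isTRUE(is_binary)),
            class = "radiograph")
}

#' @export
print.radiograph <- function(x, ...) {
  cat(sprintf("<radiograph> %d x %d px, %.4g mm/px, %s\n",
              nrow(x$intensity), ncol(x$intensity), x$pixel_spacing,
              if (x$is_binary) "binary" else "grayscale"))
  invisible(x)
}

#' Read a radiograph from PNG or TIFF
#'
#' 8/16-bit grayscale rasters; RGB(A) input is collapsed to luminance by
#' channel averaging. Intensities are normalized to [0, 1] on load.
#'
#' @param path PNG or TIFF file.
#' @param pixel_spacing mm/px of the raster.
#' @return a [radiograph()].
#' @export
read_radiograph <- function(path, pixel_spacing) {
  if (!file.exists(path)) stop("radiograph file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path),
    stop("unsupported radiograph format: .", ext))
  if (length(dim(img)) == 3L) img <- apply(img[, , 1:min(3L, dim(img)[3]),
                                               drop = FALSE], c(1, 2), mean)
  radiograph(pmin(pmax(img, 0), 1), pixel_spacing)
}

#' Write a radiograph as PNG or TIFF
#' @param img a [radiograph()].
#' @param path output path (.png, .tif/.tiff).
#' @return `path`, invisibly.
#' @export
write_radiograph <- function(img, path) {
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    png = png::writePNG(img$intensity, path),
    tif = ,
    tiff = tiff::writeTIFF(img$intensity, path, bits.per.sample = 16L),
    stop("unsupported radiograph format: .", ext))
  invisible(path)
}

#' Histogram equalization
#'
#' The standard cumulative-distribution mapping: intensities are quantized to
#' `levels` bins and each pixel is mapped to the empirical CDF value of its
#' bin, yielding an image in (0, 1]. The mapping is monotone non-decreasing,
#' so pixel ordering is preserved.
#'
#' @param img a grayscale [radiograph()].
#' @param levels number of quantization levels (default 256).
#' @return the equalized [radiograph()].
#' @export
equalize_histogram <- function(img, levels = 256L) {
  if (img$is_binary)
    stop("histogram equalization is undefined for binary radiographs")
  q <- pmin(floor(img$intensity * levels), levels - 1L)
  counts <- tabulate(q + 1L, nbins = levels)
  cdf <- cumsum(counts) / length(q)
  out <- matrix(cdf[q + 1L], nrow(img$intensity))
  radiograph(out, img$pixel_spacing, is_binary = FALSE)
}

#' Optional intensity-curve (gamma) adjustment
#'
#' Power-law remapping `out = in^gamma`; monotone for gamma > 0, so it never
#' changes a subsequent equalize-then-threshold segmentation away from bin
#' edges.
#'
#' @param img a grayscale [radiograph()].
#' @param gamma exponent, > 0.
#' @return the adjusted [radiograph()].
#' @export
adjust_gamma <- function(img, gamma = 1) {
  stopifnot(gamma > 0)
  if (img$is_binary) stop("gamma adjustment is undefined for binary radiographs")
  radiograph(img$intensity^gamma, img$pixel_spacing, is_binary = FALSE)
}

#' Threshold segmentation
#'
#' Pixels at or above the threshold (as a fraction of the [0, 1] range)
#' become 1, the rest 0. Used to segment the radiopaque prosthesis from an
#' enhanced radiograph.
#'
#' @param img a [radiograph()].
#' @param threshold fraction in (0, 1); default 0.5.
#' @return a binary [radiograph()].
#' @export
threshold_segment <- function(img, threshold = 0.5) {
  stopifnot(threshold > 0, threshold < 1)
  out <- matrix(as.numeric(img$intensity >= threshold), nrow(img$intensity))
  radiograph(out, img$pixel_spacing, is_binary = TRUE)
}

#' Region of interest from a binary segmentation
#'
#' The tight bounding box of lit pixels, enlarged by a margin and clamped to
#' the image bounds. Coordinates are 0-based pixel indices (x along columns,
#' y along rows), matching the rendering convention.
#'
#' @param seg a binary [radiograph()] (or 0/1 matrix).
#' @param margin_px non-negative margin, px.
#' @return a list `roi(x0, y0, width, height, margin)`.
#' @export
compute_roi <- function(seg, margin_px = 20L) {
  m <- if (inherits(seg, "radiograph")) seg$intensity else as.matrix(seg)
  stopifnot(margin_px >= 0)
  lit <- which(m != 0, arr.ind = TRUE)
  if (nrow(lit) == 0L) stop("empty segmentation: no lit pixels for ROI")
  y0 <- max(0L, min(lit[, 1]) - 1L - margin_px)
  y1 <- min(nrow(m) - 1L, max(lit[, 1]) - 1L + margin_px)
  x0 <- max(0L, min(lit[, 2]) - 1L - margin_px)
  x1 <- min(ncol(m) - 1L, max(lit[, 2]) - 1L + margin_px)
  structure(list(x0 = as.integer(x0), y0 = as.integer(y0),
                 width = as.integer(x1 - x0 + 1L),
                 height = as.integer(y1 - y0 + 1L),
                 margin = as.integer(margin_px)),
            class = "roi")
}

#' @export
print.roi <- function(x, ...) {
  cat(sprintf("<roi> origin (%d, %d), %d x %d px, margin %d\n",
              x$x0, x$y0, x$width, x$height, x$margin))
  invisible(x)
}

#' Crop a raster to a region of interest
#' @param img a [radiograph()], `silhouette`, mask, or plain matrix.
#' @param roi a [compute_roi()] result.
#' @return the cropped object (same type; plain matrix for matrices/masks).
#' @export
crop_roi <- function(img, roi) {
  take <- function(m) m[roi$y0 + seq_len(roi$height),
                        roi$x0 + seq_len(roi$width), drop = FALSE]
  if (inherits(img, "radiograph"))
    radiograph(take(img$intensity), img$pixel_spacing, img$is_binary)
  else take(unclass(img))
}

#' Read a drop-out mask image
#'
#' Nonzero pixels mark regions excluded from the registration (drop-outs):
#' places where the prosthesis boundary in the radiograph is unreliable,
#' e.g. occluded by an acetabular component.
#'
#' @param path PNG or TIFF mask image.
#' @param dim optional expected `c(rows, cols)`; mismatch is an error.
#' @return logical matrix, `TRUE` = excluded.
#' @export
load_mask <- function(path, dim = NULL) {
  img <- read_radiograph(path, pixel_spacing = 1)
  mask <- img$intensity > 0
  if (!is.null(dim) && !identical(base::dim(mask), as.integer(dim)))
    stop("mask dimensions do not match the radiograph")
  mask
}

#' Write a drop-out mask as PNG
#' @param mask logical matrix.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_mask <- function(mask, path) {
  png::writePNG(matrix(as.numeric(mask), nrow(mask)), path)
  invisible(path)
}
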