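#' Load a PNG or TIFF image as an 8-bit grayscale image
#'
#' RGB(A) inputs are converted to luminance with the Rec.601 weights
#' (0.299 R + 0.587 G + 0.114 B). Inputs of any stored bit depth are read
#' on the decoder's `[0, 1]` scale and rescaled to 8-bit by multiplying by
#' 255 and rounding; the original storage depth is recorded in the
#' `source_bit_depth` attribute when the decoder exposes it.
#'
#' @param path Path to a `.png`, `.tif` or `.tiff` file.
#' @return A [gray_image()] (8-bit).
#' @export
load_image <- function(path) {
  if (!file.exists(path)) {
    stop(sprintf("image file not found: '%s'", path), call. = FALSE)
  }
  ext <- tolower(tools::file_ext(path))
  arr <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path),
    stop(sprintf("unsupported image format '.%s' (PNG or TIFF expected): '%s'",
                 ext, path), call. = FALSE)
  )
  if (length(dim(arr)) == 3) {
    if (dim(arr)[3] >= 3) {
      arr <- 0.299 * arr[, , 1] + 0.587 * arr[, , 2] + 0.114 * arr[, , 3]
    } else {
      arr <- arr[, , 1]
    }
  }
  gray_image(round(arr * 255), bit_depth = 8L)
}

#' Write an 8-bit grayscale PNG
#'
#' @param img A [gray_image()] or numeric matrix on the image's intensity
#'   scale.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gray_png <- function(img, path) {
  img <- as_gray_image(img)
  png::writePNG(image_values(img) / max_intensity(img), path)
  invisible(path)
}

#' Region-of-interest rectangle
#'
#' 0-based, half-open pixel rectangle
#' `[row0, row0 + height) x [col0, col0 + width)`, mirroring how a
#' pathologist-marked ROI is recorded in a manifest.
#'
#' @param row0,col0 0-based top-left corner.
#' @param height,width Extent in pixels, each >= 2.
#' @return An object of class `roi_rect`.
#' @export
roi_rect <- function(row0, col0, height, width) {
  if (height < 2 || width < 2) {
    stop("ROI `height` and `width` must be >= 2", call. = FALSE)
  }
  if (row0 < 0 || col0 < 0) {
    stop("ROI origin must be nonnegative (0-based)", call. = FALSE)
  }
  structure(list(row0 = as.integer(row0), col0 = as.integer(col0),
                 height = as.integer(height), width = as.integer(width)),
            class = "roi_rect")
}

#' Crop an image to a region of interest
#'
#' Pixel `(r, c)` of the output equals pixel `(row0 + r, col0 + c)` of the
#' input (0-based). An ROI reaching outside the image is an error, never
#' silently clamped.
#'
#' @param img A [gray_image()].
#' @param roi A [roi_rect()].
#' @return The cropped [gray_image()].
#' @export
crop_roi <- function(img, roi) {
  img <- as_gray_image(img)
  stopifnot(inherits(roi, "roi_rect"))
  if (roi$row0 + roi$height > nrow(img) || roi$col0 + roi$width > ncol(img)) {
    stop(sprintf(
      "ROI [%d,%d) x [%d,%d) exceeds image bounds %d x %d",
      roi$row0, roi$row0 + roi$height, roi$col0, roi$col0 + roi$width,
      nrow(img), ncol(img)
    ), call. = FALSE)
  }
  vals <- image_values(img)[(roi$row0 + 1):(roi$row0 + roi$height),
                            (roi$col0 + 1):(roi$col0 + roi$width),
                            drop = FALSE]
  gray_image(vals, bit_depth = bit_depth_of(img))
}

#' Enhance image contrast
#'
#' `"stretch"` (the default used by the pipeline) linearly maps the
#' `[p_low, p_high]` percentile interval of the intensities onto the full
#' intensity range, clipping outside — a monotone, parameter-light
#' enhancement. `"equalize"` applies histogram equalisation via the
#' empirical CDF. `"none"` is the identity.
#'
#' A constant image cannot be stretched; it is returned unchanged with a
#' warning rather than dividing by zero.
#'
#' @param img A [gray_image()].
#' @param method One of `"stretch"`, `"equalize"`, `"none"`.
#' @param p_low,p_high Percentiles in `[0, 100]`, `p_low < p_high`.
#' @return The enhanced [gray_image()]; shape unchanged.
#' @export
#' @examples
#' img <- gray_image(matrix(c(50, 50, 200, 200), 2, 2))
#' range(enhance_contrast(img, "stretch", 0, 100))
enhance_contrast <- function(img, method = c("stretch", "equalize", "none"),
                             p_low = 2, p_high = 98) {
  img <- as_gray_image(img)
  method <- match.arg(method)
  if (method == "none") return(img)
  if (p_low >= p_high) stop("`p_low` must be < `p_high`", call. = FALSE)
  v <- image_values(img)
  maxval <- max_intensity(img)
  if (method == "stretch") {
    lo <- stats::quantile(v, p_low / 100, names = FALSE)
    hi <- stats::quantile(v, p_high / 100, names = FALSE)
    if (hi <= lo) {
      warning("constant (or near-constant) image: contrast stretch skipped")
      return(img)
    }
    out <- (v - lo) / (hi - lo) * maxval
    out <- pmin(pmax(out, 0), maxval)
  } else {
    cdf <- stats::ecdf(v)(v)
    cmin <- min(cdf)
    if (cmin >= 1) {
      warning("constant image: histogram equalization skipped")
      return(img)
    }
    out <- (cdf - cmin) / (1 - cmin) * maxval
    out <- matrix(out, nrow(v), ncol(v))
  }
  gray_image(out, bit_depth = bit_depth_of(img))
}
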