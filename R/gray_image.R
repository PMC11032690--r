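#' Grayscale image container
#'
#' A `gray_image` is a numeric matrix of intensities with a declared bit
#' depth; values live in `[0, 2^bit_depth - 1]` (default 8-bit, 0-255).
#' Every stage of the pipeline consumes and produces this type. Pixel
#' coordinates follow a 0-based, row-major, half-open convention in all
#' user-facing interfaces (see [roi_rect()]).
#'
#' @param values Numeric matrix, at least 2x2, all values within range.
#' @param bit_depth Integer bit depth, default 8.
#' @return An object of class `gray_image`: the matrix with a `bit_depth`
#'   attribute.
#' @export
#' @examples
#' img <- gray_image(matrix(0:255, 16, 16))
#' range(img)
gray_image <- function(values, bit_depth = 8L) {
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("`values` must be a numeric matrix", call. = FALSE)
  }
  if (nrow(values) < 2 || ncol(values) < 2) {
    stop("a gray_image must be at least 2x2", call. = FALSE)
  }
  maxval <- 2^bit_depth - 1
  if (anyNA(values) || min(values) < 0 || max(values) > maxval) {
    stop(sprintf("intensities must lie in [0, %d]", maxval), call. = FALSE)
  }
  structure(values, bit_depth = as.integer(bit_depth), class = "gray_image")
}

#' Coerce to a gray_image
#'
#' Plain numeric matrices are accepted everywhere a `gray_image` is; this
#' validates and tags them.
#'
#' @param x A `gray_image` or numeric matrix.
#' @param bit_depth Bit depth to assume for plain matrices.
#' @return A `gray_image`.
#' @export
as_gray_image <- function(x, bit_depth = 8L) {
  if (inherits(x, "gray_image")) return(x)
  gray_image(x, bit_depth = bit_depth)
}

#' @export
print.gray_image <- function(x, ...) {
  cat(sprintf(
    "<gray_image> %d x %d, %d-bit, intensity range [%.1f, %.1f]\n",
    nrow(x), ncol(x), attr(x, "bit_depth"), min(x), max(x)
  ))
  invisible(x)
}

bit_depth_of <- function(img) {
  bd <- attr(img, "bit_depth")
  if (is.null(bd)) 8L else bd
}

max_intensity <- function(img) 2^bit_depth_of(img) - 1

# Strip class/attributes down to a plain numeric matrix.
image_values <- function(img) {
  matrix(as.numeric(img), nrow(img), ncol(img))
}
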