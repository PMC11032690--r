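#' Quantize an image into discrete gray levels
#'
#' Linear equal-width binning of the interval `[lo, hi]` into `n_levels`
#' bins, clipping intensities outside the interval into the end bins.
#' With `gray_limits = NULL` ("auto") the image's own min/max are used;
#' a constant image then maps entirely to level 0, which is documented
#' behaviour, not an error.
#'
#' @param img A [gray_image()] or numeric matrix.
#' @param n_levels Number of gray levels N (>= 2).
#' @param gray_limits `c(lo, hi)` with `lo < hi`, or `NULL` for the image
#'   min/max.
#' @return An object of class `quantized_image`: list with `levels`
#'   (integer matrix in `[0, N-1]`), `n_levels`, `gray_limits`.
#' @export
#' @examples
#' q <- quantize(matrix(c(0, 255, 0, 255), 2, 2), n_levels = 2,
#'               gray_limits = c(0, 255))
#' q$levels
quantize <- function(img, n_levels = 8L, gray_limits = NULL) {
  v <- if (inherits(img, "gray_image")) image_values(img) else {
    stopifnot(is.matrix(img), is.numeric(img))
    img
  }
  if (n_levels < 2) stop("`n_levels` must be >= 2", call. = FALSE)
  auto <- is.null(gray_limits)
  if (auto) gray_limits <- range(v)
  lo <- gray_limits[1]; hi <- gray_limits[2]
  if (!auto && lo >= hi) {
    stop("`gray_limits` must satisfy lo < hi", call. = FALSE)
  }
  if (lo == hi) {
    lev <- matrix(0L, nrow(v), ncol(v))
  } else {
    lev <- floor((v - lo) / (hi - lo) * n_levels)
    lev <- matrix(as.integer(pmin(pmax(lev, 0), n_levels - 1)),
                  nrow(v), ncol(v))
  }
  structure(list(levels = lev, n_levels = as.integer(n_levels),
                 gray_limits = as.numeric(c(lo, hi))),
            class = "quantized_image")
}

#' Gray-level co-occurrence matrix
#'
#' Counts ordered pixel pairs (`(r, c)` with `(r + dr, c + dc)`) whose
#' positions are both in bounds — and, when a mask is given, both inside
#' the mask — then normalises the counts to the joint distribution
#' `p(i, j)` of their level pairs. With `symmetric = TRUE` the transpose
#' is added before normalisation, so each unordered pair is counted in
#' both directions.
#'
#' @param qimg A [quantize()]d image.
#' @param offset Integer displacement `c(dr, dc)`, not `(0, 0)`; the
#'   default `(0, 1)` pairs each pixel with its right neighbour.
#' @param mask Optional logical matrix, same shape as the image; only
#'   pairs with both ends inside the mask are counted.
#' @param symmetric Count each pair in both directions.
#' @return An object of class `glcm`: list with `p` (N x N matrix summing
#'   to 1), `offset`, `symmetric`, `pair_count`.
#' @export
compute_glcm <- function(qimg, offset = c(0L, 1L), mask = NULL,
                         symmetric = FALSE) {
  stopifnot(inherits(qimg, "quantized_image"))
  offset <- as.integer(offset)
  if (length(offset) != 2 || all(offset == 0)) {
    stop("`offset` must be a nonzero (dr, dc) displacement", call. = FALSE)
  }
  L <- qimg$levels
  N <- qimg$n_levels
  nr <- nrow(L); nc <- ncol(L)
  dr <- offset[1]; dc <- offset[2]
  rows <- max(1, 1 - dr):min(nr, nr - dr)
  cols <- max(1, 1 - dc):min(nc, nc - dc)
  if (length(rows) < 1 || length(cols) < 1) {
    stop("offset larger than the image: no valid pixel pairs", call. = FALSE)
  }
  A <- L[rows, cols, drop = FALSE]
  B <- L[rows + dr, cols + dc, drop = FALSE]
  keep <- rep(TRUE, length(A))
  if (!is.null(mask)) {
    stopifnot(identical(dim(mask), dim(L)))
    keep <- mask[rows, cols, drop = FALSE] &
      mask[rows + dr, cols + dc, drop = FALSE]
  }
  a <- A[keep]; b <- B[keep]
  if (length(a) == 0) {
    stop("no valid pixel pairs for this offset/mask", call. = FALSE)
  }
  cnt <- matrix(tabulate(a + N * b + 1L, nbins = N * N), N, N)
  if (symmetric) cnt <- cnt + t(cnt)
  structure(
    list(p = cnt / sum(cnt), offset = offset, symmetric = symmetric,
         pair_count = sum(cnt)),
    class = "glcm"
  )
}

#' The five co-occurrence texture features
#'
#' Given a normalised co-occurrence distribution `p(i, j)` over levels
#' `0..N-1`, computes (following the conventions of the classical MATLAB
#' texture functions):
#' \describe{
#'   \item{entropy}{\eqn{-\sum p \log_2 p} (bits), with `0 log 0 = 0`}
#'   \item{contrast}{\eqn{\sum (i - j)^2 p}}
#'   \item{energy}{\eqn{\sum p^2}}
#'   \item{correlation}{\eqn{\sum (i - \mu_i)(j - \mu_j) p / (\sigma_i \sigma_j)}
#'     with marginal means/SDs over the row and column indices; flagged
#'     undefined (`NA`) when either marginal variance is zero}
#'   \item{homogeneity}{\eqn{\sum p / (1 + |i - j|)}}
#' }
#'
#' @param glcm A [compute_glcm()] result, or a plain normalised N x N
#'   matrix.
#' @return A list with the five features plus `correlation_defined`.
#' @export
#' @examples
#' glcm_features(matrix(c(0.5, 0, 0, 0.5), 2, 2))
glcm_features <- function(glcm) {
  p <- if (inherits(glcm, "glcm")) glcm$p else glcm
  stopifnot(is.matrix(p), nrow(p) == ncol(p), all(p >= 0))
  if (abs(sum(p) - 1) > 1e-8) {
    stop("GLCM must be normalized to sum 1", call. = FALSE)
  }
  N <- nrow(p)
  I <- row(p) - 1
  J <- col(p) - 1
  nz <- p > 0
  entropy <- -sum(p[nz] * log2(p[nz]))
  contrast <- sum((I - J)^2 * p)
  energy <- sum(p^2)
  homogeneity <- sum(p / (1 + abs(I - J)))
  pi_ <- rowSums(p)
  pj_ <- colSums(p)
  lv <- 0:(N - 1)
  mu_i <- sum(lv * pi_); mu_j <- sum(lv * pj_)
  var_i <- sum((lv - mu_i)^2 * pi_); var_j <- sum((lv - mu_j)^2 * pj_)
  if (var_i <= 0 || var_j <= 0) {
    correlation <- NA_real_
    defined <- FALSE
  } else {
    correlation <- sum((I - mu_i) * (J - mu_j) * p) / sqrt(var_i * var_j)
    defined <- TRUE
  }
  list(entropy = entropy, contrast = contrast, energy = energy,
       correlation = correlation, homogeneity = homogeneity,
       correlation_defined = defined)
}

#' Texture features of an image in one call
#'
#' Quantizes the image, computes one GLCM per offset (optionally
#' restricted to a mask), extracts the five features per offset, and (by
#' default) averages the feature vectors across offsets. The defaults —
#' 8 levels, single offset `(0, 1)`, asymmetric — are the classical
#' defaults of MATLAB-style GLCM analysis. Unlike [quantize()]'s "auto"
#' mode, the default `gray_limits` here span the full bit-depth range
#' `(0, 255)`, so that features are comparable across images instead of
#' being renormalised to each image's own dynamic range.
#'
#' @param img A [gray_image()].
#' @param mask Optional logical foreground mask (e.g. from
#'   [segment_image()]); features are then computed from pixel pairs that
#'   lie entirely inside the mask.
#' @param n_levels,gray_limits Passed to [quantize()]; `gray_limits = NULL`
#'   here means the full bit-depth range.
#' @param offsets List of `c(dr, dc)` displacements.
#' @param symmetric Passed to [compute_glcm()].
#' @param average If `TRUE` (default) return the mean feature vector
#'   across offsets; otherwise a list of per-offset feature lists.
#' @return A one-row data.frame with the five feature columns (correlation
#'   `NA` when undefined for any offset), or a list when `average = FALSE`.
#' @export
image_features <- function(img, mask = NULL, n_levels = 8L,
                           offsets = list(c(0L, 1L)), symmetric = FALSE,
                           gray_limits = NULL, average = TRUE) {
  img <- as_gray_image(img)
  if (is.null(gray_limits)) gray_limits <- c(0, max_intensity(img))
  q <- quantize(img, n_levels = n_levels, gray_limits = gray_limits)
  per <- lapply(offsets, function(off) {
    glcm_features(compute_glcm(q, offset = off, mask = mask,
                               symmetric = symmetric))
  })
  if (!average) return(per)
  feats <- texture_feature_names()
  avg <- vapply(feats, function(f) {
    mean(vapply(per, function(x) x[[f]], numeric(1)))
  }, numeric(1))
  out <- as.data.frame(as.list(avg))
  names(out) <- feats
  out
}

#' Histogram (first-order) entropy of an image
#'
#' Shannon entropy, in bits, of the quantized intensity histogram — a
#' first-order alternative to the co-occurrence entropy, provided because
#' published "entropy" values in texture screening work are sometimes of
#' this kind.
#'
#' @inheritParams image_features
#' @return Entropy in bits.
#' @export
histogram_entropy <- function(img, mask = NULL, n_levels = 8L,
                              gray_limits = NULL) {
  img <- as_gray_image(img)
  if (is.null(gray_limits)) gray_limits <- c(0, max_intensity(img))
  q <- quantize(img, n_levels = n_levels, gray_limits = gray_limits)
  lev <- q$levels
  if (!is.null(mask)) {
    stopifnot(identical(dim(mask), dim(lev)))
    lev <- lev[mask]
  }
  p <- tabulate(lev + 1L, nbins = n_levels)
  p <- p / sum(p)
  -sum(p[p > 0] * log2(p[p > 0]))
}
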