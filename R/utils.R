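#' Derive a reproducible child seed from a master seed
#'
#' Mixes a master seed with one or more integer indices through a
#' linear-congruential step, so that subjects, images and replicates get
#' independent but fully reproducible random streams from one master seed.
#'
#' @param master Integer master seed.
#' @param ... Integer indices (subject index, image index, replicate ...).
#' @return A single integer seed in `[0, 2^31 - 2]`.
#' @export
#' @examples
#' derive_seed(1, 5)
#' derive_seed(1, 5, 2)
derive_seed <- function(master, ...) {
  idx <- c(...)
  s <- as.double(master) %% 2147483647
  for (k in idx) {
    # doubles hold these products exactly (< 2^53)
    s <- (s * 69069 + as.double(k) * 7919 + 1) %% 2147483647
  }
  as.integer(s)
}

# Evaluate `code` under a fixed seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# Row/column Gaussian smoothing operator: banded matrix with rows normalised
# to sum 1, which acts like convolution with edge renormalisation.
gaussian_band <- function(n, sigma) {
  r <- max(1L, ceiling(3 * sigma))
  d <- outer(seq_len(n), seq_len(n), "-")
  k <- exp(-(d^2) / (2 * sigma^2))
  k[abs(d) > r] <- 0
  k / rowSums(k)
}

# Separable Gaussian blur of a matrix.
blur_gaussian <- function(x, sigma) {
  if (sigma <= 0) return(x)
  kr <- gaussian_band(nrow(x), sigma)
  kc <- gaussian_band(ncol(x), sigma)
  kr %*% x %*% t(kc)
}

#' Smoothed Gaussian noise field
#'
#' White Gaussian noise smoothed with a Gaussian kernel of standard
#' deviation `grain` (pixels) and re-standardised to zero mean and unit
#' standard deviation. This is the texture primitive used inside synthetic
#' cells: `grain` sets the spatial correlation length of the fluctuations,
#' so small `grain` gives fine, rapidly varying texture and large `grain`
#' gives smooth, slowly varying texture.
#'
#' @param size Integer vector `c(rows, cols)`.
#' @param grain Correlation length in pixels; `0` leaves the noise white.
#' @param seed Integer seed; output is a pure function of `(size, grain, seed)`.
#' @return A numeric matrix with mean 0 and standard deviation 1.
#' @export
textured_field <- function(size, grain, seed) {
  stopifnot(length(size) == 2, all(size >= 2), grain >= 0)
  z <- with_seed(seed, matrix(stats::rnorm(prod(size)), size[1], size[2]))
  f <- blur_gaussian(z, grain)
  s <- stats::sd(f)
  if (s > 0) (f - mean(f)) / s else f * 0
}

#' Names of the five texture features
#'
#' @return `c("entropy", "contrast", "energy", "correlation", "homogeneity")`.
#' @export
texture_feature_names <- function() {
  c("entropy", "contrast", "energy", "correlation", "homogeneity")
}
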