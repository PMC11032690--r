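#' Fuzzy c-means clustering of intensities
#'
#' Minimises the fuzzy within-cluster objective
#' \deqn{J_m = \sum_i \sum_k u_{ik}^m (x_k - v_i)^2}
#' by alternating the standard membership update
#' \eqn{u_{ik} = 1 / \sum_j ((x_k - v_i)^2 / (x_k - v_j)^2)^{1/(m-1)}}
#' and centre update
#' \eqn{v_i = \sum_k u_{ik}^m x_k / \sum_k u_{ik}^m},
#' stopping when the largest centre shift drops below `tol` or after
#' `max_iter` iterations. A point exactly equal to a centre receives
#' membership 1 there (the usual singularity rule). Optional per-point
#' weights allow clustering the distinct intensity levels of an image with
#' their pixel counts, which is exactly equivalent to clustering every
#' pixel and much faster.
#'
#' @param values Numeric vector of P intensities, P >= c; must contain at
#'   least `c` distinct values.
#' @param c Number of clusters (>= 2).
#' @param m Fuzzifier, > 1 (default 2, the near-universal convention).
#' @param tol Convergence threshold on the maximum centre shift.
#' @param max_iter Iteration cap.
#' @param init `"quantile"` places initial centres at evenly spaced
#'   intensity quantiles (deterministic, the default); `"random"` samples
#'   `c` distinct values, controlled by `seed`.
#' @param seed Seed for `init = "random"`.
#' @param weights Optional nonnegative per-point weights (default all 1).
#' @return An object of class `fcm_fit`: list with `u` (c x P membership
#'   matrix; columns sum to 1), `centers`, `objective_trace` (J_m per
#'   iteration, non-increasing), `iterations`, `converged`.
#' @export
#' @examples
#' fit <- fcm_cluster(c(0, 0, 0, 100, 100, 100), c = 2)
#' sort(fit$centers)
fcm_cluster <- function(values, c = 2L, m = 2, tol = 1e-5, max_iter = 300L,
                        init = c("quantile", "random"), seed = NULL,
                        weights = NULL) {
  init <- match.arg(init)
  values <- as.numeric(values)
  P <- length(values)
  if (c < 2) stop("`c` must be >= 2", call. = FALSE)
  if (m <= 1) stop("fuzzifier `m` must be > 1", call. = FALSE)
  n_distinct <- length(unique(values))
  if (n_distinct < c) {
    stop(sprintf(
      "cannot form %d clusters from %d distinct intensity values",
      c, n_distinct
    ), call. = FALSE)
  }
  if (is.null(weights)) weights <- rep(1, P)
  stopifnot(length(weights) == P, all(weights >= 0), sum(weights) > 0)

  centers <- if (init == "quantile") {
    v0 <- stats::quantile(rep(values, times = round(weights / min(weights[weights > 0]))),
                          probs = (seq_len(c) - 0.5) / c, names = FALSE)
    if (anyDuplicated(v0)) v0 <- seq(min(values), max(values), length.out = c)
    v0
  } else {
    if (!is.null(seed)) set.seed(seed)
    sample(unique(values), c)
  }

  e <- 1 / (m - 1)
  trace <- numeric(0)
  converged <- FALSE
  u <- NULL
  for (it in seq_len(max_iter)) {
    d2 <- outer(values, centers, function(x, v) (x - v)^2)
    u <- memberships_from_d2(d2, e)
    um <- (u^m) * weights
    centers_new <- colSums(um * values) / colSums(um)
    # J_m evaluated after both half-updates: non-increasing by construction
    d2new <- outer(values, centers_new, function(x, v) (x - v)^2)
    trace <- c(trace, sum((u^m) * weights * d2new))
    shift <- max(abs(centers_new - centers))
    centers <- centers_new
    if (shift < tol) {
      converged <- TRUE
      break
    }
  }
  # final memberships consistent with the returned centres
  d2 <- outer(values, centers, function(x, v) (x - v)^2)
  u <- memberships_from_d2(d2, e)
  structure(
    list(u = t(u), centers = centers, objective_trace = trace,
         iterations = length(trace), converged = converged),
    class = "fcm_fit"
  )
}

# d2: P x C squared distances -> P x C membership matrix (rows sum to 1),
# with the singularity rule for zero distances.
memberships_from_d2 <- function(d2, e) {
  w <- d2^(-e)
  zero <- d2 == 0
  hit <- rowSums(zero) > 0
  if (any(hit)) {
    # if a point coincides with several centres, split evenly
    wh <- matrix(0, sum(hit), ncol(d2))
    wh[zero[hit, , drop = FALSE]] <- 1
    w[hit, ] <- wh
  }
  w / rowSums(w)
}

#' Segment an image by fuzzy c-means on pixel intensities
#'
#' Runs [fcm_cluster()] on the image's intensities (internally on the
#' distinct intensity levels weighted by their pixel counts, which gives
#' identical centres and memberships), hard-assigns each pixel to its
#' maximum-membership cluster, and returns the mask of the selected
#' cluster. The default `c = 2`, `select = "darkest"` extracts
#' PAP-stained cellular material, which is darker than the background;
#' `c = 3` separates background, cytoplasm and nuclei.
#'
#' @param img A [gray_image()].
#' @param c Number of intensity clusters.
#' @param select Which cluster becomes the mask: the one with the
#'   `"darkest"` or `"brightest"` centre, or the `"largest"` pixel count.
#' @param m,tol,max_iter Passed to [fcm_cluster()].
#' @return A logical matrix the shape of `img` (the foreground mask).
#' @export
segment_image <- function(img, c = 2L, select = c("darkest", "brightest", "largest"),
                          m = 2, tol = 1e-5, max_iter = 300L) {
  img <- as_gray_image(img)
  select <- match.arg(select)
  v <- as.vector(image_values(img))
  lev <- sort(unique(v))
  cnt <- as.numeric(table(factor(v, levels = lev)))
  fit <- fcm_cluster(lev, c = c, m = m, tol = tol, max_iter = max_iter,
                     weights = cnt)
  assign_lev <- apply(fit$u, 2, which.max)
  pix_cluster <- assign_lev[match(v, lev)]
  chosen <- switch(select,
    darkest = which.min(fit$centers),
    brightest = which.max(fit$centers),
    largest = which.max(tabulate(pix_cluster, nbins = c))
  )
  mask <- matrix(pix_cluster == chosen, nrow(img), ncol(img))
  if (!any(mask)) {
    stop("selected cluster contains no pixels: segmentation failed",
         call. = FALSE)
  }
  mask
}

#' Dice overlap between two masks
#'
#' @param a,b Logical matrices of identical shape.
#' @return Dice coefficient `2|a&b| / (|a| + |b|)`.
#' @export
dice_overlap <- function(a, b) {
  stopifnot(identical(dim(a), dim(b)))
  2 * sum(a & b) / (sum(a) + sum(b))
}
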