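#' Rendering parameters for one class of synthetic cytology images
#'
#' Describes how to draw the textured elliptical "cells" of one class
#' (healthy control or dysplastic/OSCC-like). The two shipped presets
#' ([class_preset()]) differ in the spatial correlation length and
#' amplitude of the intra-cell texture: dysplastic cells get finer grain
#' and larger intensity fluctuations, which is what drives GLCM entropy
#' and contrast up and energy, correlation and homogeneity down relative
#' to control — the direction of change reported for PAP-stained OSCC
#' smears.
#'
#' All intensities are expressed on `[0, 1]` and rendered to 8-bit.
#'
#' @param label Class label, `"control"` or `"oscc"`.
#' @param cell_count Number of cells per image (positive integer).
#' @param cell_axis_range Length-2 numeric, min/max ellipse semi-axis in
#'   pixels.
#' @param texture_grain Spatial correlation length of the intra-cell noise,
#'   in pixels (positive).
#' @param texture_amplitude Standard deviation of the intra-cell intensity
#'   fluctuation, on `[0, 1]`.
#' @param background_level Background intensity on `[0, 1]`.
#' @param nucleus_darkening Fractional darkening of the nuclear region
#'   relative to the cytoplasm, on `[0, 1]`.
#' @param cell_level Cytoplasm base intensity on `[0, 1]`; cells are darker
#'   than the background, as PAP-stained cells are.
#' @return An object of class `class_params`.
#' @seealso [class_preset()], [generate_cell_image()]
#' @export
class_params <- function(label,
                         cell_count,
                         cell_axis_range,
                         texture_grain,
                         texture_amplitude,
                         background_level,
                         nucleus_darkening,
                         cell_level = 0.45) {
  stopifnot(is.character(label), length(label) == 1)
  if (cell_count < 1) stop("`cell_count` must be >= 1", call. = FALSE)
  if (length(cell_axis_range) != 2 || any(cell_axis_range <= 0)) {
    stop("`cell_axis_range` must be two positive axis lengths", call. = FALSE)
  }
  if (texture_grain <= 0) stop("`texture_grain` must be > 0", call. = FALSE)
  if (texture_amplitude < 0 || texture_amplitude > 1) {
    stop("`texture_amplitude` must lie in [0, 1]", call. = FALSE)
  }
  if (background_level < 0 || background_level > 1 ||
      cell_level < 0 || cell_level > 1) {
    stop("intensity levels must lie in [0, 1]", call. = FALSE)
  }
  if (nucleus_darkening < 0 || nucleus_darkening > 1) {
    stop("`nucleus_darkening` must lie in [0, 1]", call. = FALSE)
  }
  structure(
    list(
      label = label,
      cell_count = as.integer(cell_count),
      cell_axis_range = sort(as.numeric(cell_axis_range)),
      texture_grain = texture_grain,
      texture_amplitude = texture_amplitude,
      background_level = background_level,
      nucleus_darkening = nucleus_darkening,
      cell_level = cell_level
    ),
    class = "class_params"
  )
}

#' Shipped class presets
#'
#' Calibrated once and fixed: the `"oscc"` preset has smaller
#' `texture_grain` and larger `texture_amplitude` than `"control"`, plus
#' stronger nuclear darkening (hyperchromatism) and a wider cell-size range
#' (pleomorphism). With these presets the five GLCM feature means over
#' images separate in the directions observed for dysplastic smears:
#' entropy and contrast higher, energy, correlation and homogeneity lower.
#'
#' @param label `"control"` or `"oscc"`.
#' @return A [class_params()] object.
#' @export
#' @examples
#' class_preset("oscc")$texture_grain < class_preset("control")$texture_grain
class_preset <- function(label = c("control", "oscc")) {
  label <- match.arg(label)
  if (label == "control") {
    class_params(
      label = "control", cell_count = 6, cell_axis_range = c(18, 28),
      texture_grain = 6, texture_amplitude = 0.06,
      background_level = 0.88, nucleus_darkening = 0.22
    )
  } else {
    class_params(
      label = "oscc", cell_count = 8, cell_axis_range = c(14, 34),
      texture_grain = 3, texture_amplitude = 0.10,
      background_level = 0.88, nucleus_darkening = 0.30
    )
  }
}

#' Per-group Gaussian specification of the five texture features
#'
#' Parameterises the per-subject feature table generator: each feature of
#' each subject is an independent Gaussian draw with the group's mean and
#' standard deviation. The defaults are the group summaries characteristic
#' of GLCM analysis of PAP-stained oral smears (80 subjects per group):
#' dysplastic smears show higher entropy and contrast and lower energy,
#' correlation and homogeneity than controls.
#'
#' @param label Group label (drives the group's random stream, so swapping
#'   two specs between argument positions swaps the generated groups
#'   exactly).
#' @param means,sds Named numeric vectors over
#'   [texture_feature_names()]; `sds` nonnegative.
#' @param n Number of subjects in the group (>= 2).
#' @return An object of class `feature_gaussian_spec`.
#' @export
#' @examples
#' feature_gaussian_spec("control")$means
feature_gaussian_spec <- function(label = c("control", "oscc"),
                                  means = NULL, sds = NULL, n = 80L) {
  defaults <- list(
    oscc = list(
      means = c(entropy = 2.05, contrast = 0.11, energy = 0.38,
                correlation = 0.94, homogeneity = 0.94),
      sds = c(entropy = 0.19, contrast = 0.03, energy = 0.04,
              correlation = 0.015, homogeneity = 0.005)
    ),
    control = list(
      means = c(entropy = 1.84, contrast = 0.06, energy = 0.40,
                correlation = 0.95, homogeneity = 0.95),
      sds = c(entropy = 0.04, contrast = 0.01, energy = 0.02,
              correlation = 0.006, homogeneity = 0.014)
    )
  )
  if (length(label) == 1 && label %in% names(defaults)) {
    base <- defaults[[label]]
  } else if (is.null(means) || is.null(sds)) {
    stop("`means` and `sds` are required for labels without shipped defaults",
         call. = FALSE)
  } else {
    base <- list(means = NULL, sds = NULL)
  }
  label <- label[1]
  feats <- texture_feature_names()
  means <- if (is.null(means)) base$means else means[feats]
  sds <- if (is.null(sds)) base$sds else sds[feats]
  if (anyNA(means) || anyNA(sds) || !all(feats %in% names(means))) {
    stop("`means` and `sds` must be named over all five features",
         call. = FALSE)
  }
  if (any(sds < 0)) stop("`sds` must be nonnegative", call. = FALSE)
  if (n < 2) stop("`n` must be >= 2 per group", call. = FALSE)
  structure(
    list(label = label, means = means[feats], sds = sds[feats],
         n = as.integer(n)),
    class = "feature_gaussian_spec"
  )
}

label_hash <- function(label) {
  sum(utf8ToInt(label) * seq_along(utf8ToInt(label)))
}

#' Generate one synthetic cytology image with its ground-truth mask
#'
#' Renders `cell_count` elliptical cells (random centre, semi-axes and
#' orientation) on a bright background. Cell interiors carry a smoothed
#' noise texture with the class's correlation length and amplitude, and a
#' concentric darker nuclear region. Cells whose ellipse extends past the
#' canvas are clipped (and counted), never dropped silently. The output is
#' a pure function of `(params, size, seed)`.
#'
#' @param params A [class_params()] object.
#' @param size Canvas dimensions `c(rows, cols)`, each >= 32.
#' @param seed Integer seed.
#' @return A list with elements `image` (8-bit [gray_image()]), `mask`
#'   (logical matrix marking rendered cell pixels), and `n_clipped`
#'   (number of cells clipped at the canvas edge).
#' @export
#' @examples
#' out <- generate_cell_image(class_preset("control"), size = c(64, 64), seed = 1)
#' mean(out$mask)
generate_cell_image <- function(params, size = c(256, 256), seed = 1L) {
  stopifnot(inherits(params, "class_params"))
  size <- as.integer(size)
  if (length(size) != 2 || any(size < 32)) {
    stop("`size` must be at least 32x32", call. = FALSE)
  }
  nr <- size[1]; nc <- size[2]
  with_seed(seed, {
    canvas <- params$background_level +
      0.015 * matrix(stats::rnorm(nr * nc), nr, nc)
    # one class-specific texture field shared by the cells of this image
    field <- blur_gaussian(matrix(stats::rnorm(nr * nc), nr, nc),
                           params$texture_grain)
    fs <- stats::sd(field)
    if (fs > 0) field <- (field - mean(field)) / fs

    rr <- matrix(seq_len(nr), nr, nc)
    cc <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
    mask <- matrix(FALSE, nr, nc)
    nucleus <- matrix(FALSE, nr, nc)
    centres <- matrix(numeric(0), ncol = 2)
    n_clipped <- 0L

    for (k in seq_len(params$cell_count)) {
      a <- stats::runif(1, params$cell_axis_range[1], params$cell_axis_range[2])
      b <- stats::runif(1, params$cell_axis_range[1], params$cell_axis_range[2])
      theta <- stats::runif(1, 0, pi)
      # rejection-sample centres to limit heavy overlap; accept after 40 tries
      for (try in 1:40) {
        cy <- stats::runif(1, 1, nr)
        cx <- stats::runif(1, 1, nc)
        if (nrow(centres) == 0) break
        dmin <- min(sqrt((centres[, 1] - cy)^2 + (centres[, 2] - cx)^2))
        if (dmin > 0.9 * max(a, b)) break
      }
      centres <- rbind(centres, c(cy, cx))
      ct <- cos(theta); st <- sin(theta)
      dx <- cc - cx; dy <- rr - cy
      u <- dx * ct + dy * st
      v <- -dx * st + dy * ct
      inside <- (u / a)^2 + (v / b)^2 <= 1
      in_nuc <- (u / (0.45 * a))^2 + (v / (0.45 * b))^2 <= 1
      mask <- mask | inside
      nucleus <- nucleus | in_nuc
      ex <- sqrt((a * ct)^2 + (b * st)^2)
      ey <- sqrt((a * st)^2 + (b * ct)^2)
      if (cx - ex < 1 || cx + ex > nc || cy - ey < 1 || cy + ey > nr) {
        n_clipped <- n_clipped + 1L
      }
    }

    cellint <- params$cell_level * (1 - params$nucleus_darkening * nucleus) +
      params$texture_amplitude * field
    canvas[mask] <- cellint[mask]
    canvas <- pmin(pmax(canvas, 0), 1)
    img <- gray_image(round(canvas * 255), bit_depth = 8L)
    list(image = img, mask = mask, n_clipped = n_clipped)
  })
}

#' Generate a per-subject Gaussian feature table
#'
#' Each subject's five features are independent Gaussian draws with the
#' group's means and standard deviations. Each group's random stream is
#' keyed to `(seed, group label)`, so the draws attached to a label do not
#' depend on argument position: swapping the two specs swaps the generated
#' group summaries exactly.
#'
#' @param spec_a,spec_b [feature_gaussian_spec()] objects for the two
#'   groups (defaults: control and OSCC-like at the shipped parameters,
#'   80 subjects each).
#' @param seed Integer master seed.
#' @return A data.frame with columns `subject_id`, `group` and the five
#'   features; `spec_a`'s rows first.
#' @export
#' @examples
#' tab <- generate_feature_table(seed = 1)
#' aggregate(entropy ~ group, tab, mean)
generate_feature_table <- function(spec_a = feature_gaussian_spec("control"),
                                   spec_b = feature_gaussian_spec("oscc"),
                                   seed = 1L) {
  stopifnot(inherits(spec_a, "feature_gaussian_spec"),
            inherits(spec_b, "feature_gaussian_spec"))
  one_group <- function(spec) {
    draws <- with_seed(derive_seed(seed, label_hash(spec$label)), {
      vapply(texture_feature_names(), function(f) {
        stats::rnorm(spec$n, spec$means[[f]], spec$sds[[f]])
      }, numeric(spec$n))
    })
    draws <- matrix(draws, nrow = spec$n,
                    dimnames = list(NULL, texture_feature_names()))
    data.frame(
      subject_id = sprintf("%s_s%03d", spec$label, seq_len(spec$n)),
      group = spec$label,
      draws,
      stringsAsFactors = FALSE
    )
  }
  rbind(one_group(spec_a), one_group(spec_b))
}

#' Generate a labelled synthetic cohort of cytology images on disk
#'
#' Writes 8-bit grayscale PNG images (several per subject, emulating
#' multiple manually cropped fields per smear) plus a CSV manifest with
#' columns `subject_id`, `group`, `image_path` (paths relative to
#' `out_dir`). The default configuration — 80 subjects per group, 10
#' images each — produces 1600 images. Per-image seeds are derived
#' deterministically from the master seed, the global subject index and
#' the image index, so cohorts are bit-reproducible and subjects
#' independent.
#'
#' @param out_dir Output directory (created if needed; must be writable).
#' @param n_per_group Subjects per group (>= 1).
#' @param images_per_subject Images per subject (>= 1).
#' @param params Named list with elements `control` and `oscc`, each a
#'   [class_params()] object.
#' @param size Image dimensions `c(rows, cols)`.
#' @param seed Integer master seed.
#' @param write_masks Also write ground-truth masks as 0/255 PNGs.
#' @return The manifest data.frame, invisibly written to
#'   `file.path(out_dir, "manifest.csv")`.
#' @export
generate_cohort <- function(out_dir,
                            n_per_group = 80L,
                            images_per_subject = 10L,
                            params = list(control = class_preset("control"),
                                          oscc = class_preset("oscc")),
                            size = c(256, 256),
                            seed = 1L,
                            write_masks = FALSE) {
  if (n_per_group < 1 || images_per_subject < 1) {
    stop("`n_per_group` and `images_per_subject` must be >= 1", call. = FALSE)
  }
  stopifnot(all(c("control", "oscc") %in% names(params)))
  img_dir <- file.path(out_dir, "images")
  dir.create(img_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(img_dir)) {
    stop(sprintf("cannot create output directory '%s'", out_dir), call. = FALSE)
  }
  rows <- vector("list", 2L * n_per_group * images_per_subject)
  ridx <- 0L
  for (g in c("control", "oscc")) {
    goff <- if (g == "control") 0L else n_per_group
    for (i in seq_len(n_per_group)) {
      sid <- sprintf("%s_s%03d", g, i)
      for (j in seq_len(images_per_subject)) {
        out <- generate_cell_image(params[[g]], size = size,
                                   seed = derive_seed(seed, goff + i, j))
        rel <- file.path("images", sprintf("%s_img%02d.png", sid, j))
        write_gray_png(out$image, file.path(out_dir, rel))
        if (write_masks) {
          mrel <- file.path("images", sprintf("%s_img%02d_mask.png", sid, j))
          write_gray_png(gray_image(out$mask * 255), file.path(out_dir, mrel))
        }
        ridx <- ridx + 1L
        rows[[ridx]] <- data.frame(subject_id = sid, group = g,
                                   image_path = rel, stringsAsFactors = FALSE)
      }
    }
  }
  manifest <- do.call(rbind, rows)
  utils::write.csv(manifest, file.path(out_dir, "manifest.csv"),
                   row.names = FALSE)
  invisible(manifest)
}
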