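# Independent brute-force co-occurrence pair counter: a literal double loop
# over pixel positions, kept deliberately naive so it cannot share a defect
# with the vectorised implementation it checks.
brute_force_glcm <- function(levels, n_levels, offset, mask = NULL,
                             symmetric = FALSE) {
  nr <- nrow(levels); nc <- ncol(levels)
  cnt <- matrix(0, n_levels, n_levels)
  for (r in seq_len(nr)) {
    for (c in seq_len(nc)) {
      r2 <- r + offset[1]; c2 <- c + offset[2]
      if (r2 < 1 || r2 > nr || c2 < 1 || c2 > nc) next
      if (!is.null(mask) && (!mask[r, c] || !mask[r2, c2])) next
      i <- levels[r, c] + 1; j <- levels[r2, c2] + 1
      cnt[i, j] <- cnt[i, j] + 1
    }
  }
  if (symmetric) cnt <- cnt + t(cnt)
  if (sum(cnt) == 0) return(NULL)
  cnt / sum(cnt)
}

# Small flat-cell parameter set: no intra-cell variation at all.
flat_params <- function(label = "control") {
  class_params(label, cell_count = 3, cell_axis_range = c(8, 12),
               texture_grain = 3, texture_amplitude = 0,
               background_level = 0.9, nucleus_darkening = 0)
}

# Tiny-cell presets for fast small-canvas cohorts in tests.
small_params <- function() {
  list(
    control = class_params("control", cell_count = 3,
                           cell_axis_range = c(5, 8), texture_grain = 4,
                           texture_amplitude = 0.06, background_level = 0.88,
                           nucleus_darkening = 0.22),
    oscc = class_params("oscc", cell_count = 4, cell_axis_range = c(4, 9),
                        texture_grain = 1.5, texture_amplitude = 0.10,
                        background_level = 0.88, nucleus_darkening = 0.30)
  )
}

expect_feature_equal <- function(f, expected, tol = 1e-12) {
  for (nm in names(expected)) {
    if (is.na(expected[[nm]])) {
      expect_true(is.na(f[[nm]]), label = paste(nm, "should be undefined"))
    } else {
      expect_equal(f[[nm]], expected[[nm]], tolerance = tol,
                   label = paste("feature", nm))
    }
  }
}
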