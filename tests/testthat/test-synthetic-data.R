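test_that("generate_cell_image is a pure function of (params, size, seed)", {
  p <- class_preset("control")
  a <- generate_cell_image(p, size = c(64, 64), seed = 11)
  b <- generate_cell_image(p, size = c(64, 64), seed = 11)
  expect_identical(image_values(a$image), image_values(b$image))
  expect_identical(a$mask, b$mask)
  c <- generate_cell_image(p, size = c(64, 64), seed = 12)
  expect_false(identical(image_values(a$image), image_values(c$image)))
})

test_that("flat cells (no texture, no nuclear darkening) have zero masked contrast", {
  out <- generate_cell_image(flat_params(), size = c(64, 64), seed = 2)
  inside <- image_values(out$image)[out$mask]
  expect_equal(length(unique(inside)), 1)
  f <- image_features(out$image, mask = out$mask)
  expect_equal(f$contrast, 0)
})

test_that("mask marks exactly the rendered cell pixels", {
  p <- flat_params()
  out <- generate_cell_image(p, size = c(64, 64), seed = 4)
  cell_val <- round(p$cell_level * 255)
  expect_true(all(image_values(out$image)[out$mask] == cell_val))
  # background stays near background_level, far from the cell intensity
  expect_true(all(image_values(out$image)[!out$mask] > 0.75 * 255))
})

test_that("degenerate cell parameters are rejected; clipping is reported", {
  expect_error(class_params("x", 3, c(0, 10), 3, 0.1, 0.9, 0.2),
               "positive axis")
  expect_error(class_params("x", 0, c(5, 10), 3, 0.1, 0.9, 0.2),
               "cell_count")
  expect_error(generate_cell_image(flat_params(), size = c(16, 16)),
               "32x32")
  # huge cells on a small canvas must clip and say so
  big <- class_params("big", cell_count = 4, cell_axis_range = c(30, 40),
                      texture_grain = 3, texture_amplitude = 0.05,
                      background_level = 0.9, nucleus_darkening = 0.2)
  out <- generate_cell_image(big, size = c(64, 64), seed = 1)
  expect_gt(out$n_clipped, 0)
})

test_that("shipped presets order all five feature means as in dysplastic smears", {
  feats <- function(preset) {
    do.call(rbind, lapply(1:50, function(s) {
      out <- generate_cell_image(class_preset(preset), size = c(128, 128),
                                 seed = s)
      image_features(out$image, mask = out$mask)
    }))
  }
  fc <- colMeans(feats("control"))
  fo <- colMeans(feats("oscc"))
  expect_gt(fo[["entropy"]], fc[["entropy"]])
  expect_gt(fo[["contrast"]], fc[["contrast"]])
  expect_lt(fo[["energy"]], fc[["energy"]])
  expect_lt(fo[["correlation"]], fc[["correlation"]])
  expect_lt(fo[["homogeneity"]], fc[["homogeneity"]])
})

test_that("preset invariant: oscc has finer grain and larger amplitude", {
  ctrl <- class_preset("control"); osc <- class_preset("oscc")
  expect_lt(osc$texture_grain, ctrl$texture_grain)
  expect_gt(osc$texture_amplitude, ctrl$texture_amplitude)
})

test_that("feature tables hit their Gaussian parameters", {
  tab <- generate_feature_table(seed = 1)
  expect_equal(nrow(tab), 160)
  expect_equal(sum(tab$group == "oscc"), 80)
  # sample mean within 3 standard errors of the generator's own parameters
  m <- mean(tab$entropy[tab$group == "oscc"])
  expect_lt(abs(m - 2.05), 3 * 0.19 / sqrt(80))

  # sd = 0 collapses every subject onto the group means
  z <- feature_gaussian_spec("oscc", sds = c(entropy = 0, contrast = 0,
                                             energy = 0, correlation = 0,
                                             homogeneity = 0))
  tz <- generate_feature_table(feature_gaussian_spec("control"), z, seed = 3)
  expect_true(all(tz$entropy[tz$group == "oscc"] == 2.05))
  expect_true(all(tz$homogeneity[tz$group == "oscc"] == 0.94))
})

test_that("swapping the two specs swaps the generated groups exactly", {
  a <- feature_gaussian_spec("control")
  b <- feature_gaussian_spec("oscc")
  t1 <- generate_feature_table(a, b, seed = 9)
  t2 <- generate_feature_table(b, a, seed = 9)
  for (g in c("control", "oscc")) {
    expect_equal(t1[t1$group == g, ], t2[t2$group == g, ],
                 ignore_attr = TRUE)
  }
})

test_that("parameter recovery: summaries converge to the spec as n grows", {
  big <- generate_feature_table(
    feature_gaussian_spec("control", n = 8000),
    feature_gaussian_spec("oscc", n = 8000), seed = 2
  )
  sm <- summarize_groups(big)
  spec <- feature_gaussian_spec("oscc")
  for (f in texture_feature_names()) {
    row <- sm[sm$feature == f & sm$group == "oscc", ]
    expect_lt(abs(row$mean - spec$means[[f]]),
              5 * spec$sds[[f]] / sqrt(8000))
    expect_lt(abs(row$sd - spec$sds[[f]]), 0.05 * spec$sds[[f]] + 1e-6)
  }
})

test_that("generate_cohort writes the manifest and images it promises", {
  tmp <- withr::local_tempdir()
  man <- generate_cohort(tmp, n_per_group = 2, images_per_subject = 3,
                         params = small_params(), size = c(48, 48), seed = 5)
  expect_equal(nrow(man), 12)
  expect_named(man, c("subject_id", "group", "image_path"))
  expect_true(all(file.exists(file.path(tmp, man$image_path))))
  expect_true(file.exists(file.path(tmp, "manifest.csv")))

  # same seed into a second directory: identical manifests and pixel data
  tmp2 <- withr::local_tempdir()
  man2 <- generate_cohort(tmp2, n_per_group = 2, images_per_subject = 3,
                          params = small_params(), size = c(48, 48), seed = 5)
  expect_identical(man, man2)
  sums1 <- unname(tools::md5sum(file.path(tmp, man$image_path)))
  sums2 <- unname(tools::md5sum(file.path(tmp2, man2$image_path)))
  expect_identical(sums1, sums2)
})

test_that("the default cohort structure yields 1600 manifest rows", {
  tmp <- withr::local_tempdir()
  man <- generate_cohort(tmp, n_per_group = 80, images_per_subject = 10,
                         params = small_params(), size = c(32, 32), seed = 1)
  expect_equal(nrow(man), 1600)
  expect_equal(length(unique(man$subject_id)), 160)
  expect_equal(sum(man$group == "control"), 800)
})
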