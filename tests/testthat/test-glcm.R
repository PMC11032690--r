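test_that("quantize bins linearly, clips, and is idempotent on levels", {
  q <- quantize(matrix(c(0, 255, 0, 255), 2, 2), n_levels = 2,
                gray_limits = c(0, 255))
  expect_identical(sort(unique(as.vector(q$levels))), c(0L, 1L))

  ramp <- matrix(0:255, 16, 16)
  q8 <- quantize(ramp, n_levels = 8, gray_limits = c(0, 255))
  expect_equal(as.vector(table(q8$levels)), rep(32, 8))

  # re-quantizing already-quantized levels with matching limits is identity
  q2 <- quantize(q8$levels, n_levels = 8, gray_limits = c(0, 7))
  expect_identical(q2$levels, q8$levels)

  # constant image with auto limits maps to level 0, not an error
  qc <- quantize(matrix(42, 4, 4), n_levels = 8)
  expect_true(all(qc$levels == 0L))

  expect_error(quantize(ramp, n_levels = 1), "n_levels")
  expect_error(quantize(ramp, n_levels = 8, gray_limits = c(5, 5)), "lo < hi")
})

test_that("compute_glcm reproduces hand-enumerated 2x2 cases", {
  q <- structure(list(levels = matrix(c(0L, 1L, 0L, 1L), 2, 2),
                      n_levels = 2L, gray_limits = c(0, 1)),
                 class = "quantized_image")
  # image rows [[0,0],[1,1]]: two horizontal pairs (0,0) and (1,1)
  g <- compute_glcm(q, offset = c(0, 1))
  expect_equal(g$p, matrix(c(0.5, 0, 0, 0.5), 2, 2))
  expect_equal(g$pair_count, 2)

  chk <- structure(list(levels = matrix(c(0L, 1L, 1L, 0L), 2, 2),
                        n_levels = 2L, gray_limits = c(0, 1)),
                   class = "quantized_image")
  g2 <- compute_glcm(chk, offset = c(0, 1))
  expect_equal(g2$p, matrix(c(0, 0.5, 0.5, 0), 2, 2))
})

test_that("compute_glcm matches the brute-force pair counter", {
  offsets <- list(c(0, 1), c(1, 0), c(1, 1), c(1, -1))
  set.seed(42)
  for (rep in 1:30) {
    nr <- sample(2:8, 1); nc <- sample(2:8, 1)
    N <- sample(2:5, 1)
    lev <- matrix(sample(0:(N - 1), nr * nc, replace = TRUE), nr, nc)
    q <- structure(list(levels = lev, n_levels = N, gray_limits = c(0, N - 1)),
                   class = "quantized_image")
    mask <- matrix(runif(nr * nc) > 0.3, nr, nc)
    for (off in offsets) {
      for (sym in c(FALSE, TRUE)) {
        expect_equal(compute_glcm(q, off, symmetric = sym)$p,
                     brute_force_glcm(lev, N, off, symmetric = sym),
                     tolerance = 1e-12)
        oracle <- brute_force_glcm(lev, N, off, mask = mask, symmetric = sym)
        if (is.null(oracle)) {
          expect_error(compute_glcm(q, off, mask = mask, symmetric = sym),
                       "no valid pixel pairs")
        } else {
          expect_equal(compute_glcm(q, off, mask = mask, symmetric = sym)$p,
                       oracle, tolerance = 1e-12)
        }
      }
    }
  }
})

test_that("compute_glcm rejects degenerate inputs", {
  q <- quantize(matrix(0:15, 4, 4), n_levels = 4, gray_limits = c(0, 15))
  expect_error(compute_glcm(q, offset = c(0, 0)), "nonzero")
  expect_error(compute_glcm(q, offset = c(0, 1),
                            mask = matrix(FALSE, 4, 4)), "no valid")
})

test_that("glcm_features matches hand-computed closed forms", {
  expect_feature_equal(
    glcm_features(matrix(c(0.5, 0, 0, 0.5), 2, 2)),
    list(entropy = 1, contrast = 0, energy = 0.5, correlation = 1,
         homogeneity = 1)
  )
  expect_feature_equal(
    glcm_features(matrix(c(0, 0.5, 0.5, 0), 2, 2)),
    list(entropy = 1, contrast = 1, energy = 0.5, correlation = -1,
         homogeneity = 0.5)
  )
  f <- glcm_features(matrix(c(1, 0, 0, 0), 2, 2))
  expect_feature_equal(
    f, list(entropy = 0, contrast = 0, energy = 1, correlation = NA,
            homogeneity = 1)
  )
  expect_false(f$correlation_defined)
  expect_error(glcm_features(matrix(c(0.5, 0.5, 0.5, 0.5), 2, 2)),
               "normalized")
})

test_that("features respect their theoretical ranges on random GLCMs", {
  set.seed(7)
  for (rep in 1:50) {
    N <- sample(2:8, 1)
    p <- matrix(rexp(N * N), N, N)
    p <- p / sum(p)
    f <- glcm_features(p)
    expect_gte(f$entropy, 0)
    expect_lte(f$entropy, 2 * log2(N) + 1e-12)
    expect_gte(f$contrast, 0)
    expect_lte(f$contrast, (N - 1)^2)
    expect_gt(f$energy, 0)
    expect_lte(f$energy, 1)
    expect_gt(f$homogeneity, 0)
    expect_lte(f$homogeneity, 1)
    if (f$correlation_defined) {
      expect_gte(f$correlation, -1 - 1e-12)
      expect_lte(f$correlation, 1 + 1e-12)
    }
  }
})

test_that("symmetric-GLCM correlation is invariant under offset negation", {
  set.seed(11)
  img <- gray_image(matrix(sample(0:255, 400, replace = TRUE), 20, 20))
  q <- quantize(img, 8, c(0, 255))
  for (off in list(c(0, 1), c(1, 0), c(1, 1))) {
    f1 <- glcm_features(compute_glcm(q, off, symmetric = TRUE))
    f2 <- glcm_features(compute_glcm(q, -off, symmetric = TRUE))
    expect_equal(f1$correlation, f2$correlation, tolerance = 1e-12)
  }
})

test_that("image_features composes the stages and averages over offsets", {
  set.seed(3)
  img <- gray_image(matrix(sample(0:255, 16 * 16, replace = TRUE), 16, 16))
  f <- image_features(img)
  manual <- glcm_features(compute_glcm(quantize(img, 8, c(0, 255)), c(0, 1)))
  expect_equal(f$entropy, manual$entropy)
  expect_equal(f$correlation, manual$correlation)

  # constant image: contrast 0, energy 1 under any config
  fc <- image_features(gray_image(matrix(100, 8, 8)))
  expect_equal(fc$contrast, 0)
  expect_equal(fc$energy, 1)

  # 4-offset isotropy on generator output: per-offset contrasts within
  # 10% of their mean
  out <- generate_cell_image(class_preset("oscc"), size = c(128, 128),
                             seed = 5)
  per <- image_features(out$image, mask = out$mask,
                        offsets = list(c(0, 1), c(1, 0), c(1, 1), c(1, -1)),
                        average = FALSE)
  ctr <- vapply(per, `[[`, numeric(1), "contrast")
  # isotropy: equal-length offsets (axial pair, diagonal pair) agree ~10%
  expect_lt(abs(ctr[1] - ctr[2]) / mean(ctr[1:2]), 0.1)
  expect_lt(abs(ctr[3] - ctr[4]) / mean(ctr[3:4]), 0.1)
})

test_that("increasing noise amplitude moves all five features monotonically", {
  amps <- c(0.01, 0.05, 0.12)
  mean_feats <- vapply(amps, function(a) {
    f <- do.call(rbind, lapply(1:30, function(s) {
      smooth <- 0.5 + 0.15 * textured_field(c(48, 48), grain = 6, seed = s)
      noise <- textured_field(c(48, 48), grain = 0, seed = derive_seed(s, 1))
      img <- gray_image(round(pmin(pmax(smooth + a * noise, 0), 1) * 255))
      unlist(image_features(img))
    }))
    colMeans(f)
  }, numeric(5))
  expect_true(all(diff(mean_feats["entropy", ]) > 0))
  expect_true(all(diff(mean_feats["contrast", ]) > 0))
  expect_true(all(diff(mean_feats["energy", ]) < 0))
  expect_true(all(diff(mean_feats["correlation", ]) < 0))
  expect_true(all(diff(mean_feats["homogeneity", ]) < 0))
})

test_that("histogram entropy is zero for constant and maximal for uniform levels", {
  expect_equal(histogram_entropy(gray_image(matrix(10, 8, 8))), 0)
  ramp <- gray_image(matrix(0:255, 16, 16))
  expect_equal(histogram_entropy(ramp, n_levels = 8, gray_limits = c(0, 255)),
               3)
})
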