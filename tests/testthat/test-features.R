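test_that("patch registration respects count, bounds and determinism", {
  img <- matrix(rnorm(64 * 64), 64, 64)
  ps <- extract_patches(img, n_patches = 20, patch_px = 16, seed = 3)
  expect_length(ps$patches, 20)
  tr <- ps$transforms
  expect_true(all(tr$row0 >= 0 & tr$row0 + 16 <= 64))
  expect_true(all(tr$col0 >= 0 & tr$col0 + 16 <= 64))
  expect_true(all(tr$rotation %in% c(0, 90, 180, 270)))
  ps2 <- extract_patches(img, n_patches = 20, patch_px = 16, seed = 3)
  expect_identical(ps$transforms, ps2$transforms)
  expect_identical(ps$patches, ps2$patches)
  expect_error(extract_patches(img, patch_px = 100), "exceeds")
})

test_that("GLCM features match hand-derived special cases", {
  # constant patch: single-cell matrix
  f <- glcm_features(matrix(7, 8, 8))
  expect_equal(unname(f), c(0, 1, 1))
  # 8x8 binary checkerboard, horizontal offset only: all pairs are (0,1)
  cb <- outer(1:8, 1:8, function(i, j) (i + j) %% 2)
  f <- glcm_features(cb, levels = 8, distance = 1, angles = 0)
  expect_equal(f[["entropy_glcm"]], 1)
  expect_equal(f[["energy_glcm"]], 0.5)
  expect_equal(f[["homogeneity_glcm"]], 0.5)
})

test_that("GLCM features equal a brute-force pair-counting oracle", {
  set.seed(10)
  for (i in 1:25) {
    patch <- matrix(sample.int(12, 64, replace = TRUE), 8, 8)
    expect_equal(unname(glcm_features(patch)), unname(oracle_glcm(patch)),
                 tolerance = 1e-12)
    fpatch <- matrix(rnorm(64), 8, 8)
    expect_equal(unname(glcm_features(fpatch)), unname(oracle_glcm(fpatch)),
                 tolerance = 1e-12)
  }
})

test_that("GLCM features are invariant to additive offsets and bounded", {
  set.seed(11)
  patch <- matrix(rnorm(256), 16, 16)
  f1 <- glcm_features(patch)
  f2 <- glcm_features(patch + 17.3)
  expect_equal(f1, f2, tolerance = 1e-12)
  expect_lte(f1[["entropy_glcm"]], log2(64))
  expect_gt(f1[["energy_glcm"]], 0); expect_lte(f1[["energy_glcm"]], 1)
  expect_gt(f1[["homogeneity_glcm"]], 0)
  expect_lte(f1[["homogeneity_glcm"]], 1)
  expect_error(glcm_features(matrix(c(1, NA, 2, 3), 2, 2)), "non-finite")
})

test_that("histogram features match hand computations and the oracle", {
  # constant patch
  f <- histogram_features(matrix(3, 4, 4))
  expect_equal(unname(f), c(3, 1, 0, 3, 0, 0, 0, 0))
  # equal counts of {0, 2}
  patch <- matrix(c(0, 2), 8, 8)
  f <- histogram_features(patch)
  expect_equal(f[["mean"]], 1)
  expect_equal(f[["variance"]], 1)
  expect_equal(f[["std"]], 1)
  expect_equal(f[["rms"]], sqrt(2))
  expect_equal(f[["skewness"]], 0)
  expect_equal(f[["kurtosis"]], 1)
  expect_equal(f[["contrast"]], 1)
  expect_equal(f[["energy_hist"]], 0.5)
  # random patches vs direct-formula oracle
  set.seed(12)
  for (i in 1:25) {
    p <- matrix(rnorm(64, 5, 2), 8, 8)
    expect_equal(unname(histogram_features(p)), unname(oracle_histogram(p)),
                 tolerance = 1e-10)
  }
})

test_that("histogram moments scale correctly under affine maps", {
  set.seed(13)
  x <- matrix(runif(100, 1, 4), 10, 10)
  f <- histogram_features(x)
  g <- histogram_features(3 * x + 2)
  expect_equal(g[["mean"]], 3 * f[["mean"]] + 2, tolerance = 1e-12)
  expect_equal(g[["std"]], 3 * f[["std"]], tolerance = 1e-12)
  expect_equal(g[["variance"]], 9 * f[["variance"]], tolerance = 1e-12)
  expect_equal(g[["skewness"]], f[["skewness"]], tolerance = 1e-12)
  expect_equal(g[["kurtosis"]], f[["kurtosis"]], tolerance = 1e-12)
})

test_that("feature presets select the documented image types", {
  expect_equal(feature_preset(1), "raman_1437")
  expect_equal(feature_preset(7), c("raman_1437", "af_1437"))
  expect_equal(feature_preset(8), c("raman_1655", "af_1655"))
  expect_length(feature_preset(9), 4)
  expect_error(feature_preset(10), "1..9")
})

test_that("feature table has the documented shape and provenance columns", {
  p <- quiet_params()
  ds <- generate_dataset(2, seed = 8, image_px = 48, field_cm = 1.4)
  sep <- separate_dataset(ds, ratio_source = "truth")
  ft <- build_feature_table(sep, n_patches = 5, patch_px = 24, seed = 1)
  expect_s3_class(ft, "feature_table")
  expect_equal(nrow(ft), 6 * 5)
  feat_cols <- setdiff(names(ft), c("label", "group", "patch"))
  expect_length(feat_cols, 44)  # 11 features x 4 image types
  expect_true(all(grepl("^(raman|af)_(1437|1655)_", feat_cols)))
  expect_false(anyNA(ft))
  # preset row 1: only raman_1437 columns
  ft1 <- build_feature_table(sep, selection = feature_preset(1),
                             n_patches = 5, patch_px = 24, seed = 1)
  expect_length(setdiff(names(ft1), c("label", "group", "patch")), 11)
  expect_true(all(grepl("^raman_1437_",
                        setdiff(names(ft1), c("label", "group", "patch")))))
  # patch transforms shared across image types: identical means imply the
  # same windows were cut from proportional raman/af images
  expect_error(build_feature_table(sep, selection = "raman_9999"),
               "nonempty subset")
  sep_broken <- sep
  sep_broken[[1]]$images$af_1655 <- NULL
  expect_error(build_feature_table(sep_broken, n_patches = 2,
                                   patch_px = 24), "missing image type")
})

test_that("feature extraction is deterministic given a seed", {
  p <- quiet_params()
  ds <- generate_dataset(1, seed = 3, image_px = 48)
  sep <- separate_dataset(ds, ratio_source = "truth")
  f1 <- build_feature_table(sep, n_patches = 4, patch_px = 20, seed = 9)
  f2 <- build_feature_table(sep, n_patches = 4, patch_px = 20, seed = 9)
  expect_identical(f1, f2)
})
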