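make_set <- function(a, b, band = 1437) {
  band_image_set(band, a, b)
}

test_that("estimate_k solves the ratio-matching equation in closed form", {
  a <- matrix(200, 10, 10)
  b <- matrix(100, 10, 10)
  k <- estimate_k(make_set(a, b), target_ratio = 1)
  expect_equal(k, 1)  # mean AF = mean Raman = 100
  # large-ratio limit: k -> mean(A)/mean(B)
  k_inf <- estimate_k(make_set(a, b), target_ratio = 1e9)
  expect_equal(k_inf, 2, tolerance = 1e-8)
  # k increases with r for fixed images
  rs <- c(0.5, 1, 2, 5, 20, 100)
  ks <- vapply(rs, function(r) estimate_k(make_set(a, b), r), 0)
  expect_true(all(diff(ks) > 0))
  expect_error(estimate_k(make_set(a, matrix(0, 10, 10)), 1), "positive")
  expect_error(estimate_k(make_set(a, b), -2), "positive")
})

test_that("true k of noise-free phantoms is recovered to 1e-3", {
  p <- quiet_params()
  sp <- generate_spectrum(p, seed = 21)
  for (band in c(1437, 1655)) {
    for (s in 1:10) {
      k_true <- 0.5 + 1.5 * (s - 1) / 9
      bs <- render_band_image_set(sp, band, p, seed = s, image_px = 32,
                                  k_true = k_true)
      k <- estimate_k(bs, bs$ground_truth$target_ratio)
      expect_lt(abs(k - k_true) / k_true, 1e-3,
                label = sprintf("band %d seed %d k error", band, s))
    }
  }
})

test_that("separation reproduces proportional-image closed forms", {
  a <- matrix(runif(400, 1, 2), 20, 20)
  s1 <- separate(make_set(a, a), target_ratio = 1)
  expect_equal(s1$k, 0.5)
  expect_equal(s1$raman_image, 0.5 * a, tolerance = 1e-12)
  s2 <- separate(make_set(a, a), target_ratio = 1e12)
  expect_lt(max(abs(s2$raman_image)) / max(a), 1e-9)
})

test_that("separation conserves intensity before clamping", {
  p <- phantom_class_table()$BENIGN
  sp <- generate_spectrum(p, seed = 31)
  bs <- render_band_image_set(sp, 1437, p, seed = 31, image_px = 48)
  res <- separate(bs, bs$ground_truth$target_ratio)
  expect_equal(res$raman_unclamped + res$af_image_scaled, bs$signal_image,
               tolerance = 1e-12)
  expect_true(all(res$raman_image >= 0))
  expect_gte(res$clamped_fraction, 0)
  expect_lte(res$clamped_fraction, 1)
  expect_equal(res$achieved_ratio, res$target_ratio, tolerance = 1e-9)
})

test_that("noise-free separation recovers the true Raman image", {
  p <- quiet_params("STS")
  sp <- generate_spectrum(p, seed = 41)
  for (band in c(1437, 1655)) {
    bs <- render_band_image_set(sp, band, p, seed = 3, image_px = 48)
    res <- separate(bs, bs$ground_truth$target_ratio)
    rel <- sqrt(sum((res$raman_image - bs$ground_truth$raman_image)^2) /
                  sum(bs$ground_truth$raman_image^2))
    expect_lt(rel, 1e-6)
  }
})

test_that("coefficient of variation follows its definition", {
  expect_equal(coefficient_of_variation(matrix(5, 4, 4)), 0)
  img <- matrix(c(1, 3, 1, 3), 2, 2)
  expect_equal(coefficient_of_variation(img), 0.5)  # sd population / mean = 1/2
  zm <- matrix(c(-1, 1, -1, 1), 2, 2)
  expect_error(coefficient_of_variation(zm), "zero mean")
  expect_error(coefficient_of_variation(matrix(1, 1, 1)), "at least 2")
})

test_that("cv_ratio contrasts lesion texture against surround", {
  img <- matrix(rnorm(400, 10, 1), 20, 20)
  left <- col(img) <= 10
  expect_equal(cv_ratio(img, left, !left), 1, tolerance = 0.5)
  expect_error(cv_ratio(img, left, left), "disjoint")
  flat <- img; flat[!left] <- 2
  expect_error(cv_ratio(flat, left, !left), "zero|undefined")
  # lesion with doubled texture amplitude yields ratio > 1 in most draws
  hits <- 0
  for (s in 1:20) {
    set.seed(s)
    base <- matrix(10, 24, 24)
    noise <- matrix(rnorm(576), 24, 24)
    lesion <- col(base) <= 12
    im <- base + noise * ifelse(lesion, 2, 1)
    if (cv_ratio(im, lesion, !lesion) > 1) hits <- hits + 1
  }
  expect_gte(hits, 17)
})

test_that("2-level k-means segmentation finds a bright disk", {
  n <- 64
  cx <- (row(matrix(0, n, n)) - n / 2)^2 + (col(matrix(0, n, n)) - n / 2)^2
  disk <- cx <= (n / 4)^2
  set.seed(99)
  img <- ifelse(disk, 10, 1) + matrix(rnorm(n * n, 0, 0.3), n, n)
  mask <- segment_lesion(img, seed = 1)
  expect_gte(mean(mask == disk), 0.99)
  expect_identical(mask, segment_lesion(img, seed = 1))
  expect_error(segment_lesion(matrix(3, 5, 5)), "constant")
})
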