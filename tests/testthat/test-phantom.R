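test_that("class parameter invariants are enforced", {
  good <- phantom_class_table()$MCT
  expect_s3_class(good, "tissue_class_params")
  bad <- function(...) {
    args <- utils::modifyList(unclass(good), list(...))
    do.call(tissue_class_params, args[names(formals(tissue_class_params))])
  }
  expect_error(bad(raman_peak_amplitudes = rep(1, 3)), "equal length")
  expect_error(bad(raman_peak_centers = rev(good$raman_peak_centers)),
               "strictly increasing")
  expect_error(bad(af_level = 2), "\\[10, 100\\]")
  expect_error(bad(af_level = 500), "\\[10, 100\\]")
  expect_error(bad(af_decay = -0.01), "positive")
  expect_error(bad(af_level = NaN), "non-finite")
})

test_that("AF continuum decays strictly over 1300-1750 and dominates Raman", {
  for (cl in c("MCT", "STS", "BENIGN")) {
    p <- phantom_class_table()[[cl]]
    for (s in 1:5) {
      sp <- generate_spectrum(p, seed = s)
      wn <- sp$wavenumbers
      af <- sp$ground_truth$autofluorescence
      sel <- wn >= 1300 & wn <= 1750
      expect_true(all(diff(af[sel]) < 0),
                  label = sprintf("%s seed %d AF decreasing", cl, s))
      ratio <- af[wn == 1437] / max(p$raman_peak_amplitudes)
      expect_gte(ratio, 10)
      expect_lte(ratio, 100)
    }
  }
})

test_that("the 1437 band is the most intense Raman feature", {
  p <- quiet_params("MCT")
  sp <- generate_spectrum(p, seed = 1)
  wn <- sp$wavenumbers
  total <- sp$intensities
  af <- sp$ground_truth$autofluorescence
  at <- function(v, c) v[which.min(abs(wn - c))]
  others <- setdiff(p$raman_peak_centers, 1437)
  for (c2 in others)
    expect_gt(at(total, 1437), at(total, c2) - at(af, c2))
})

test_that("zero AF level yields exactly the sum of Gaussian peaks", {
  p <- quiet_params()
  p$af_level <- 0
  p2 <- do.call(tissue_class_params, unclass(p)[names(formals(tissue_class_params))])
  sp <- generate_spectrum(p2, seed = 4)
  peaks <- rep(0, length(sp$wavenumbers))
  for (i in seq_along(p2$raman_peak_centers))
    peaks <- peaks + p2$raman_peak_amplitudes[i] *
      exp(-4 * log(2) * (sp$wavenumbers - p2$raman_peak_centers[i])^2 /
            p2$raman_peak_widths[i]^2)
  expect_equal(sp$intensities, peaks, tolerance = 1e-12)
})

test_that("band image rendering obeys its construction contract", {
  p <- quiet_params()
  sp <- generate_spectrum(p, seed = 6)
  n <- 32
  flat <- matrix(1, n, n)
  # uniform illumination, unit texture, zero noise: every signal pixel is
  # the band integral of Raman + AF over the signal window
  bs <- render_band_image_set(sp, 1437, p, seed = 6, image_px = n,
                              illumination = flat, texture = flat,
                              k_true = 1.2)
  gt <- bs$ground_truth
  expected <- gt$integral_raman + gt$integral_af_signal
  expect_equal(as.vector(bs$signal_image), rep(expected, n * n),
               tolerance = 1e-12)
  # direct integration of the stored spectrum reproduces the image means
  wins <- band_window_pair(1437)
  i_r <- band_integral(sp$wavenumbers, sp$ground_truth$raman, wins$signal)
  i_af <- band_integral(sp$wavenumbers, sp$ground_truth$autofluorescence,
                        wins$signal)
  i_af2 <- band_integral(sp$wavenumbers, sp$ground_truth$autofluorescence,
                         wins$af)
  expect_equal(mean(bs$signal_image) / mean(bs$af_image),
               (i_r + i_af) / (i_af2 * gt$gain), tolerance = 1e-2)
  # AF fields spatially proportional: A - raman_truth = k_true * B exactly
  bs2 <- render_band_image_set(sp, 1437, p, seed = 8, image_px = n,
                               k_true = 0.8)
  expect_equal(bs2$signal_image - bs2$ground_truth$raman_image,
               0.8 * bs2$af_image, tolerance = 1e-10)
  expect_equal(bs2$ground_truth$k_true, 0.8)
})

test_that("rendered images are nonnegative before noise, almost after", {
  p <- phantom_class_table()$STS
  sp <- generate_spectrum(p, seed = 9)
  bs <- render_band_image_set(sp, 1655, p, seed = 9, image_px = 64)
  expect_true(all(bs$ground_truth$signal_image_noisefree >= 0))
  expect_true(all(bs$ground_truth$af_image_noisefree >= 0))
  expect_lt(mean(bs$signal_image < 0), 0.01)
  expect_lt(mean(bs$af_image < 0), 0.01)
})

test_that("datasets have the right size and are seed-deterministic", {
  ds <- generate_dataset(1, seed = 2, image_px = 24)
  expect_length(ds, 3)
  expect_setequal(vapply(ds, `[[`, "", "class_label"),
                  c("MCT", "STS", "BENIGN"))
  ds2 <- generate_dataset(2, seed = 5, image_px = 24)
  expect_length(ds2, 6)
  ds3 <- generate_dataset(2, seed = 5, image_px = 24)
  expect_identical(ds2, ds3)
  ds4 <- generate_dataset(2, seed = 6, image_px = 24)
  expect_false(identical(ds2, ds4))
  expect_error(generate_dataset(0), ">= 1")
})

test_that("null class table removes between-class differences", {
  tab <- phantom_class_table(separation = 0)
  expect_equal(tab$MCT$raman_peak_amplitudes, tab$STS$raman_peak_amplitudes)
  expect_equal(tab$MCT$af_level, tab$BENIGN$af_level)
  expect_equal(tab$STS$texture_amplitude, tab$BENIGN$texture_amplitude)
  # labels still differ
  expect_equal(tab$MCT$class_label, "MCT")
})

test_that("illumination profile has unit mean and positive values", {
  for (s in 1:3) {
    prof <- illumination_profile(48, seed = s)
    expect_equal(mean(prof), 1, tolerance = 1e-9)
    expect_gt(min(prof), 0)
  }
})
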