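#' Tissue-class parameters for the optical phantom generator
#'
#' Bundles the spectral and spatial parameters that define one synthetic
#' tissue class: Gaussian Raman peak positions/amplitudes/widths, the
#' autofluorescence continuum level at 1437 cm^-1 and its exponential decay
#' rate, the spatial texture statistics of the rendered band images, and
#' noise levels.
#'
#' @param class_label Class name, conventionally one of "MCT", "STS",
#'   "BENIGN".
#' @param raman_peak_centers Strictly increasing peak positions (cm^-1)
#'   within [1200, 1800].
#' @param raman_peak_amplitudes Peak heights (a.u.), all > 0.
#' @param raman_peak_widths Peak FWHMs (cm^-1).
#' @param af_level Autofluorescence amplitude at 1437 cm^-1 (a.u.). Must be
#'   10-100 times the largest Raman amplitude (autofluorescence dominates
#'   Raman scattering by one to two orders of magnitude).
#' @param af_decay Exponential decay rate of the continuum toward higher
#'   wavenumbers (per cm^-1), > 0.
#' @param af_poly_orders Candidate orders of the smooth log-domain
#'   perturbation superimposed on the exponential continuum (drawn per
#'   spectrum), so baseline fitting faces more than a pure exponential.
#' @param texture_correlation_length Correlation length of the Gaussian
#'   random texture field (pixels).
#' @param texture_amplitude Relative amplitude of the texture field
#'   (dimensionless).
#' @param noise_sigma Additive Gaussian noise on spectra (a.u.).
#' @param image_noise_rel Additive Gaussian image noise, sigma relative to
#'   each image's noise-free mean.
#' @param k_range Range the true autofluorescence calibration constant k is
#'   drawn from per band image set.
#' @return An object of class \code{tissue_class_params}.
#' @export
tissue_class_params <- function(class_label,
                                raman_peak_centers,
                                raman_peak_amplitudes,
                                raman_peak_widths,
                                af_level,
                                af_decay,
                                af_poly_orders = 2:5,
                                texture_correlation_length = 10,
                                texture_amplitude = 0.15,
                                noise_sigma = 0.02,
                                image_noise_rel = 2e-4,
                                k_range = c(0.5, 2)) {
  p <- list(class_label = class_label,
            raman_peak_centers = as.numeric(raman_peak_centers),
            raman_peak_amplitudes = as.numeric(raman_peak_amplitudes),
            raman_peak_widths = as.numeric(raman_peak_widths),
            af_level = af_level, af_decay = af_decay,
            af_poly_orders = as.integer(af_poly_orders),
            texture_correlation_length = texture_correlation_length,
            texture_amplitude = texture_amplitude,
            noise_sigma = noise_sigma,
            image_noise_rel = image_noise_rel,
            k_range = as.numeric(k_range))
  nums <- unlist(p[-c(1, 7)])
  if (any(!is.finite(nums))) stop("non-finite phantom parameters")
  nc <- length(p$raman_peak_centers)
  if (length(p$raman_peak_amplitudes) != nc ||
      length(p$raman_peak_widths) != nc)
    stop("peak center/amplitude/width lists must have equal length")
  if (any(diff(p$raman_peak_centers) <= 0) ||
      any(p$raman_peak_centers < 1200) || any(p$raman_peak_centers > 1800))
    stop("peak centers must be strictly increasing within [1200, 1800] cm-1")
  if (any(p$raman_peak_amplitudes <= 0) || any(p$raman_peak_widths <= 0))
    stop("peak amplitudes and widths must be positive")
  ratio <- p$af_level / max(p$raman_peak_amplitudes)
  if (p$af_level != 0 && (ratio < 10 || ratio > 100))
    stop("af_level / max Raman amplitude must lie in [10, 100], got ",
         format(ratio, digits = 3),
         " (af_level = 0 is allowed as the degenerate AF-free case)")
  if (p$af_decay <= 0) stop("af_decay must be positive")
  if (length(p$k_range) != 2 || any(p$k_range <= 0) ||
      p$k_range[1] > p$k_range[2])
    stop("k_range must be a positive increasing pair")
  structure(p, class = "tissue_class_params")
}

# Band assignments represented in every phantom class (cm-1):
# lipids/proteins CH2/CH3 (1437/1447), amide C=O / lipid C=C (1652/1655),
# collagen and tertiary amides (1239, 1301, 1315, 1342), guanine (1315),
# formalin (1490), tryptophan (1552), phenylalanine (1602), primary amides
# (1628), lipids (1745).
.phantom_peak_centers <- c(1239, 1301, 1315, 1342, 1437, 1490, 1552,
                           1602, 1628, 1655, 1745)
.phantom_peak_widths <- c(14, 12, 10, 13, 18, 10, 11, 10, 12, 14, 13)

#' Default phantom class table
#'
#' Three tissue classes (mast cell tumor, soft tissue sarcoma, benign
#' tissue) that differ in Raman peak amplitudes (MCT strongest, STS
#' weakest, with the CH2/CH3 band at 1437 cm^-1 dominating in all), in
#' autofluorescence level and decay (STS the strongest emitter), and in
#' image texture statistics. \code{separation} linearly scales the
#' between-class differences around the class mean: 1 gives the default
#' classes, 0 makes all three classes statistically identical (the null
#' configuration used for calibration checks).
#'
#' @param separation Between-class effect scale in [0, 1+].
#' @return Named list of \code{\link{tissue_class_params}}.
#' @export
phantom_class_table <- function(separation = 1) {
  amp <- list(
    MCT    = c(0.28, 0.40, 0.32, 0.35, 1.00, 0.22, 0.18, 0.16, 0.24, 0.55, 0.20),
    STS    = c(0.22, 0.30, 0.26, 0.30, 0.70, 0.20, 0.14, 0.13, 0.20, 0.42, 0.16),
    BENIGN = c(0.25, 0.36, 0.28, 0.32, 0.90, 0.21, 0.16, 0.15, 0.22, 0.60, 0.25))
  af_level <- c(MCT = 25, STS = 42, BENIGN = 16)
  af_decay <- c(MCT = 0.006, STS = 0.008, BENIGN = 0.012)
  tex_len <- c(MCT = 6, STS = 14, BENIGN = 10)
  tex_amp <- c(MCT = 0.20, STS = 0.12, BENIGN = 0.16)

  amp_mean <- Reduce(`+`, amp) / 3
  blend <- function(v, m) m + separation * (v - m)
  out <- lapply(names(amp), function(cl) {
    a <- blend(amp[[cl]], amp_mean)
    tissue_class_params(
      class_label = cl,
      raman_peak_centers = .phantom_peak_centers,
      raman_peak_amplitudes = a,
      raman_peak_widths = .phantom_peak_widths,
      af_level = blend(af_level[[cl]], mean(af_level)),
      af_decay = blend(af_decay[[cl]], mean(af_decay)),
      texture_correlation_length = blend(tex_len[[cl]], mean(tex_len)),
      texture_amplitude = blend(tex_amp[[cl]], mean(tex_amp)),
      noise_sigma = 0.02,
      image_noise_rel = 2e-4)
  })
  names(out) <- names(amp)
  out
}

# derive a bounded per-item seed from a user seed
.sub_seed <- function(seed, i) {
  as.integer((as.numeric(seed) * 2654435.0 + i * 40503.0) %% 2147483647)
}

#' Generate a synthetic single-point spectrum with known decomposition
#'
#' The intensity trace is the sum of (i) a smooth autofluorescence
#' continuum -- an exponential decay in wavenumber modulated by a small
#' random low-order polynomial in the log domain, constrained so the
#' continuum is strictly decreasing over the axis -- (ii) Gaussian Raman
#' peaks, and (iii) i.i.d. Gaussian noise. The noiseless Raman and
#' autofluorescence components are stored as ground truth.
#'
#' @param params A \code{\link{tissue_class_params}}.
#' @param axis Wavenumber grid (cm^-1), strictly increasing, covering
#'   [1200, 1800].
#' @param seed Integer seed.
#' @param sample_id Optional identifier.
#' @return A \code{\link{raman_spectrum}} with a \code{ground_truth} element
#'   (lists \code{raman} and \code{autofluorescence}).
#' @export
generate_spectrum <- function(params, axis = seq(1200, 1800, by = 1),
                              seed = 1, sample_id = NA_character_) {
  stopifnot(inherits(params, "tissue_class_params"))
  axis <- as.numeric(axis)
  if (any(diff(axis) <= 0)) stop("axis must be strictly increasing")
  if (axis[1] > 1200 || axis[length(axis)] < 1800)
    stop("axis must cover [1200, 1800] cm-1")
  set.seed(.sub_seed(seed, 1L))

  # log-domain perturbation, slope-limited so the continuum stays decreasing
  m <- if (length(params$af_poly_orders) == 1) params$af_poly_orders else
    sample(params$af_poly_orders, 1)
  tt <- 2 * (axis - axis[1]) / (axis[length(axis)] - axis[1]) - 1
  co <- stats::rnorm(m)
  q <- as.numeric(cbind(stats::poly(tt, m)) %*% co)
  dq <- diff(q) / diff(axis)
  frac <- stats::runif(1, 0.2, 0.6)
  s <- if (max(abs(dq)) > 0) frac * params$af_decay / max(abs(dq)) else 0
  i0 <- which.min(abs(axis - 1437))
  expo <- -params$af_decay * (axis - 1437) + s * (q - q[i0])
  af <- params$af_level * exp(expo)

  raman <- rep(0, length(axis))
  for (i in seq_along(params$raman_peak_centers)) {
    w <- params$raman_peak_widths[i]
    raman <- raman + params$raman_peak_amplitudes[i] *
      exp(-4 * log(2) * (axis - params$raman_peak_centers[i])^2 / w^2)
  }
  noise <- if (params$noise_sigma > 0)
    stats::rnorm(length(axis), 0, params$noise_sigma) else 0
  sp <- raman_spectrum(axis, af + raman + noise, sample_id = sample_id,
                       class_label = params$class_label)
  sp$ground_truth <- list(raman = raman, autofluorescence = af)
  sp
}

#' Gaussian random field with given correlation length
#'
#' White noise smoothed by a periodic Gaussian kernel (FFT convolution),
#' standardized to zero mean and unit standard deviation.
#'
#' @param n Field side length (pixels).
#' @param corr_len Kernel standard deviation (pixels).
#' @param seed Integer seed.
#' @return n x n numeric matrix.
#' @export
gaussian_random_field <- function(n, corr_len, seed = 1) {
  set.seed(.sub_seed(seed, 2L))
  z <- matrix(stats::rnorm(n * n), n, n)
  if (corr_len <= 0) return((z - mean(z)) / stats::sd(z))
  d <- pmin(0:(n - 1), n - (0:(n - 1)))  # wrapped distance
  g <- exp(-d^2 / (2 * corr_len^2))
  ker <- outer(g, g)
  f <- Re(stats::fft(stats::fft(z) * stats::fft(ker), inverse = TRUE)) / n^2
  (f - mean(f)) / stats::sd(as.vector(f))
}

#' Non-uniform illumination profile
#'
#' A smooth multiplicative Gaussian vignette with slight random decentering,
#' normalized to unit mean; all values are strictly positive.
#'
#' @param n Field side length (pixels).
#' @param seed Integer seed.
#' @param width Vignette standard deviation relative to the field size.
#' @return n x n matrix with mean 1.
#' @export
illumination_profile <- function(n, seed = 1, width = 0.6) {
  set.seed(.sub_seed(seed, 3L))
  cx <- n / 2 + stats::runif(1, -0.08, 0.08) * n
  cy <- n / 2 + stats::runif(1, -0.08, 0.08) * n
  x <- seq_len(n)
  prof <- exp(-(outer((x - cy)^2, (x - cx)^2, `+`)) / (2 * (width * n)^2))
  prof / mean(prof)
}

#' Construct a band image set
#'
#' The paired filter-position images for one spectral band: the
#' signal-position image (Raman peak plus autofluorescence; '0-R' for the
#' 1437 cm^-1 band, 'R-0' for 1655 cm^-1) and the shifted
#' autofluorescence-position image ('R-R' / '0-0').
#'
#' @param band 1437 or 1655.
#' @param signal_image,af_image 2-D intensity matrices of equal shape.
#' @param sample_id,class_label Optional metadata.
#' @param ground_truth Optional list of generator ground truth.
#' @return An object of class \code{band_image_set}.
#' @export
band_image_set <- function(band, signal_image, af_image,
                           sample_id = NA_character_,
                           class_label = NA_character_,
                           ground_truth = NULL) {
  band <- as.numeric(band)
  if (!band %in% c(1437, 1655)) stop("band must be 1437 or 1655")
  if (!identical(dim(signal_image), dim(af_image)))
    stop("signal and AF images must have the same shape")
  if (any(!is.finite(signal_image)) || any(!is.finite(af_image)))
    stop("image intensities must be finite")
  pos <- band_window_pair(band)
  structure(
    list(band_label = band,
         signal_position = pos$signal$position,
         af_position = pos$af$position,
         signal_image = signal_image, af_image = af_image,
         sample_id = sample_id, class_label = class_label,
         ground_truth = ground_truth),
    class = "band_image_set")
}

#' @export
print.band_image_set <- function(x, ...) {
  cat(sprintf("Band image set %g cm-1 ('%s' / '%s'), %d x %d px\n",
              x$band_label, x$signal_position, x$af_position,
              nrow(x$signal_image), ncol(x$signal_image)))
  invisible(x)
}

#' Render the paired filter-position images for one band
#'
#' Each pixel of the signal-position image is
#' illumination x texture x [band integral of the Raman trace + band
#' integral of the autofluorescence over the signal window], plus noise;
#' the autofluorescence-position image carries the autofluorescence
#' integral over its own window, scaled by an instrument gain chosen so
#' the true calibration constant k equals \code{k_true}. The two
#' autofluorescence fields are spatially proportional, so a single
#' spatially uniform true k exists by construction and is recorded in the
#' ground truth together with the noise-free component images.
#'
#' @param spectrum A generated spectrum carrying \code{ground_truth}
#'   (see \code{\link{generate_spectrum}}).
#' @param band 1437 or 1655.
#' @param params The \code{\link{tissue_class_params}} used.
#' @param seed Integer seed.
#' @param image_px Image side length (pixels).
#' @param illumination Optional illumination matrix (unit mean); generated
#'   from the seed if NULL.
#' @param texture Optional texture matrix; generated from the seed if NULL.
#' @param k_true True calibration constant; drawn from \code{params$k_range}
#'   if NULL.
#' @return A \code{\link{band_image_set}} with ground truth.
#' @export
render_band_image_set <- function(spectrum, band, params, seed = 1,
                                  image_px = 256, illumination = NULL,
                                  texture = NULL, k_true = NULL) {
  stopifnot(inherits(spectrum, "raman_spectrum"))
  if (is.null(spectrum$ground_truth))
    stop("spectrum must carry a ground-truth decomposition")
  wins <- band_window_pair(band)
  wn <- spectrum$wavenumbers
  gt <- spectrum$ground_truth
  i_r <- band_integral(wn, gt$raman, wins$signal)
  i_af_sig <- band_integral(wn, gt$autofluorescence, wins$signal)
  i_af_af <- band_integral(wn, gt$autofluorescence, wins$af)

  set.seed(.sub_seed(seed, 4L + as.integer(band)))
  if (is.null(k_true)) k_true <- stats::runif(1, params$k_range[1],
                                              params$k_range[2])
  if (k_true <= 0) stop("k_true must be positive")
  if (is.null(illumination)) illumination <- illumination_profile(image_px,
                                                                  seed = seed)
  if (is.null(texture)) {
    gf <- gaussian_random_field(image_px, params$texture_correlation_length,
                                seed = .sub_seed(seed, 11L + as.integer(band)))
    texture <- pmax(1 + params$texture_amplitude * gf, 0.05)
  }
  field <- illumination * texture
  gain <- i_af_sig / (i_af_af * k_true)
  raman_true <- field * i_r
  af_sig_true <- field * i_af_sig
  b0 <- field * i_af_af * gain
  a0 <- raman_true + af_sig_true
  nrel <- params$image_noise_rel
  a <- a0
  b <- b0
  if (nrel > 0) {
    a <- a0 + stats::rnorm(length(a0), 0, nrel * mean(a0))
    b <- b0 + stats::rnorm(length(b0), 0, nrel * mean(b0))
  }
  band_image_set(
    band, matrix(a, image_px), matrix(b, image_px),
    sample_id = spectrum$sample_id, class_label = params$class_label,
    ground_truth = list(
      k_true = k_true, gain = gain,
      raman_image = raman_true, af_signal_image = af_sig_true,
      af_image_noisefree = b0, signal_image_noisefree = a0,
      integral_raman = i_r, integral_af_signal = i_af_sig,
      integral_af_af = i_af_af,
      target_ratio = i_af_sig / i_r))
}

#' Generate a full phantom sample
#'
#' One synthetic tissue sample: a single-point spectrum plus the paired
#' band image sets at 1437 and 1655 cm^-1 sharing one illumination
#' profile, with complete ground truth.
#'
#' @param params A \code{\link{tissue_class_params}}.
#' @param sample_id Identifier.
#' @param seed Integer seed.
#' @param image_px Image side length (pixels).
#' @param field_cm Physical field of view represented by the image (cm).
#' @param axis Wavenumber grid.
#' @return An object of class \code{phantom_sample}.
#' @export
generate_phantom_sample <- function(params, sample_id, seed = 1,
                                    image_px = 256, field_cm = 1.4,
                                    axis = seq(1200, 1800, by = 1)) {
  sp <- generate_spectrum(params, axis = axis, seed = seed,
                          sample_id = sample_id)
  illum <- illumination_profile(image_px, seed = seed)
  bands <- lapply(c(1437, 1655), function(b)
    render_band_image_set(sp, b, params, seed = seed, image_px = image_px,
                          illumination = illum))
  names(bands) <- c("1437", "1655")
  structure(
    list(sample_id = sample_id, class_label = params$class_label,
         spectrum = sp, bands = bands, illumination = illum,
         image_px = image_px, field_cm = field_cm),
    class = "phantom_sample")
}

#' Generate a labeled multi-class phantom dataset
#'
#' Draws \code{n_per_class} independent samples per tissue class.
#' Deterministic given the seed.
#'
#' @param n_per_class Samples per class, >= 1.
#' @param class_param_table Named list of \code{\link{tissue_class_params}}
#'   (default \code{\link{phantom_class_table}()}).
#' @param seed Integer seed.
#' @param image_px Image side length (pixels).
#' @param field_cm Physical field of view (cm).
#' @param axis Wavenumber grid.
#' @return An object of class \code{phantom_dataset} (list of
#'   \code{phantom_sample}).
#' @export
generate_dataset <- function(n_per_class, class_param_table = phantom_class_table(),
                             seed = 1, image_px = 256, field_cm = 1.4,
                             axis = seq(1200, 1800, by = 1)) {
  if (n_per_class < 1) stop("n_per_class must be >= 1")
  if (is.null(names(class_param_table)) ||
      !all(vapply(class_param_table, inherits, TRUE, "tissue_class_params")))
    stop("class_param_table must be a named list of tissue_class_params")
  samples <- list()
  idx <- 0L
  for (cl in names(class_param_table)) {
    for (i in seq_len(n_per_class)) {
      idx <- idx + 1L
      sid <- sprintf("%s_%02d", cl, i)
      samples[[sid]] <- generate_phantom_sample(
        class_param_table[[cl]], sid, seed = .sub_seed(seed, 100L + idx),
        image_px = image_px, field_cm = field_cm, axis = axis)
    }
  }
  structure(samples, class = "phantom_dataset",
            seed = seed, n_per_class = n_per_class)
}

#' @export
print.phantom_dataset <- function(x, ...) {
  cls <- vapply(x, `[[`, "", "class_label")
  cat("Phantom dataset:", length(x), "samples (",
      paste(sprintf("%s: %d", names(table(cls)), table(cls)), collapse = ", "),
      ")\n")
  invisible(x)
}
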