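.rot90 <- function(m, times = 1) {
  times <- times %% 4
  for (i in seq_len(times)) m <- t(m)[ncol(m):1, , drop = FALSE]
  m
}

#' Draw patch registration transforms
#'
#' Uniform random integer translations plus rotations drawn from
#' {0, 90, 180, 270} degrees (axis-aligned only, so no interpolation
#' alters the texture statistics). Deterministic given the seed.
#'
#' @param image_dim Image dimensions (rows, cols).
#' @param n_patches Number of patches (default 20).
#' @param patch_px Patch side length (pixels), <= min(image_dim).
#' @param seed Integer seed.
#' @return data.frame with columns row0, col0 (0-based offsets), rotation
#'   (degrees).
#' @export
patch_transforms <- function(image_dim, n_patches = 20, patch_px, seed = 1) {
  if (patch_px > min(image_dim))
    stop("patch_px (", patch_px, ") exceeds image size (",
         paste(image_dim, collapse = "x"), ")")
  set.seed(seed)
  data.frame(
    row0 = sample.int(image_dim[1] - patch_px + 1, n_patches,
                      replace = TRUE) - 1L,
    col0 = sample.int(image_dim[2] - patch_px + 1, n_patches,
                      replace = TRUE) - 1L,
    rotation = sample(c(0L, 90L, 180L, 270L), n_patches, replace = TRUE))
}

#' Register patches from an image
#'
#' Extracts \code{n_patches} square patches by random translation and
#' 90-degree rotations (see \code{\link{patch_transforms}}); patches may
#' overlap and every patch lies fully inside the image bounds.
#'
#' @param image 2-D intensity matrix.
#' @param n_patches Number of patches (default 20).
#' @param patch_px Patch side length (pixels).
#' @param seed Integer seed (ignored when \code{transforms} is supplied).
#' @param transforms Optional precomputed transform table, so the same
#'   registration can be applied to several image types of one sample.
#' @return An object of class \code{patch_set}: list with \code{patches}
#'   (list of matrices) and \code{transforms}.
#' @export
extract_patches <- function(image, n_patches = 20, patch_px, seed = 1,
                            transforms = NULL) {
  if (is.null(transforms))
    transforms <- patch_transforms(dim(image), n_patches, patch_px, seed)
  patches <- lapply(seq_len(nrow(transforms)), function(i) {
    r0 <- transforms$row0[i]; c0 <- transforms$col0[i]
    p <- image[r0 + seq_len(patch_px), c0 + seq_len(patch_px), drop = FALSE]
    .rot90(p, transforms$rotation[i] %/% 90L)
  })
  structure(list(patches = patches, transforms = transforms,
                 patch_px = patch_px, seed = seed),
            class = "patch_set")
}

#' Gray-level co-occurrence texture features
#'
#' The patch is quantized to at most \code{levels} gray levels (integer
#' patches whose range fits within \code{levels} keep their own gray
#' levels; others are min-max quantized); symmetric
#' co-occurrence matrices at the given offset distance and angles are
#' normalized and averaged; from the averaged matrix P:
#' entropy = -sum p log2 p (bits, 0 log 0 := 0), energy = sum p^2,
#' homogeneity = sum p / (1 + |i - j|).
#'
#' @param patch 2-D matrix with >= 2 pixels, finite values.
#' @param levels Number of gray levels (default 8).
#' @param distance Offset distance in pixels (default 1).
#' @param angles Offset angles in degrees, subset of {0, 45, 90, 135}.
#' @return Named numeric vector (entropy_glcm, energy_glcm,
#'   homogeneity_glcm).
#' @export
glcm_features <- function(patch, levels = 8, distance = 1,
                          angles = c(0, 45, 90, 135)) {
  if (length(patch) < 2) stop("patch must have at least 2 pixels")
  if (any(!is.finite(patch))) stop("patch contains non-finite pixels")
  q <- .quantize(patch, levels)
  offs <- list(`0` = c(0L, 1L), `45` = c(-1L, 1L), `90` = c(-1L, 0L),
               `135` = c(-1L, -1L))
  if (!all(as.character(angles) %in% names(offs)))
    stop("angles must be drawn from {0, 45, 90, 135}")
  n <- nrow(q); m <- ncol(q)
  pavg <- matrix(0, levels, levels)
  used <- 0L
  for (ang in as.character(angles)) {
    dr <- offs[[ang]][1] * distance
    dc <- offs[[ang]][2] * distance
    r1 <- seq(max(1, 1 - dr), min(n, n - dr))
    c1 <- seq(max(1, 1 - dc), min(m, m - dc))
    if (!length(r1) || !length(c1)) next
    a <- q[r1, c1, drop = FALSE]
    b <- q[r1 + dr, c1 + dc, drop = FALSE]
    counts <- tabulate((a - 1L) * levels + b, nbins = levels * levels)
    cm <- matrix(counts, levels, levels, byrow = TRUE)  # cm[a, b]
    cm <- cm + t(cm)
    pavg <- pavg + cm / sum(cm)
    used <- used + 1L
  }
  if (used == 0L) stop("no valid pixel pairs for the requested offsets")
  p <- pavg / used
  nz <- p[p > 0]
  ij <- abs(row(p) - col(p))
  c(entropy_glcm = -sum(nz * log2(nz)),
    energy_glcm = sum(p^2),
    homogeneity_glcm = sum(p / (1 + ij)))
}

# integer patches whose value range already fits within `levels` keep their
# gray levels (shifted to 1-based), so a binary image occupies two adjacent
# levels; anything else is min-max quantized onto the full level range
.quantize <- function(x, levels) {
  lo <- min(x); hi <- max(x)
  if (hi == lo) return(matrix(1L, nrow(x), ncol(x)))
  if (all(x == round(x)) && (hi - lo) < levels)
    return(matrix(as.integer(x - lo + 1), nrow(x), ncol(x)))
  q <- floor((x - lo) / (hi - lo) * levels) + 1L
  q[q > levels] <- levels
  matrix(as.integer(q), nrow(x), ncol(x))
}

#' First-order histogram features of a patch
#'
#' mean; population standard deviation and variance; RMS =
#' sqrt(mean(x^2)); skewness m3/sigma^3 and (Pearson, non-excess) kurtosis
#' m4/sigma^4, both defined as 0 when sigma = 0; Michelson contrast
#' (max - min)/(max + min) with min/max read at the 1st/99th intensity
#' percentiles for outlier resistance (0 when max + min = 0); histogram
#' energy = sum p^2 over a \code{bins}-bin normalized histogram spanning
#' the patch's min-max range.
#'
#' @param patch 2-D matrix with >= 2 pixels, finite values.
#' @param bins Histogram bins for the energy feature (default 256).
#' @return Named numeric vector (mean, energy_hist, std, rms, contrast,
#'   variance, skewness, kurtosis).
#' @export
histogram_features <- function(patch, bins = 256) {
  x <- as.numeric(patch)
  if (length(x) < 2) stop("patch must have at least 2 pixels")
  if (any(!is.finite(x))) stop("patch contains non-finite pixels")
  mu <- mean(x)
  v <- mean((x - mu)^2)
  s <- sqrt(v)
  skew <- if (s > 0) mean((x - mu)^3) / s^3 else 0
  kurt <- if (s > 0) mean((x - mu)^4) / s^4 else 0
  qs <- stats::quantile(x, c(0.01, 0.99), names = FALSE)
  contrast <- if (qs[1] + qs[2] == 0) 0 else (qs[2] - qs[1]) / (qs[2] + qs[1])
  lo <- min(x); hi <- max(x)
  energy <- if (hi == lo) 1 else {
    breaks <- seq(lo, hi, length.out = bins + 1)
    idx <- findInterval(x, breaks, all.inside = TRUE)
    p <- tabulate(idx, bins) / length(x)
    sum(p^2)
  }
  c(mean = mu, energy_hist = energy, std = s, rms = sqrt(mean(x^2)),
    contrast = contrast, variance = v, skewness = skew, kurtosis = kurt)
}

#' All eleven texture/histogram features of a patch
#'
#' @inheritParams glcm_features
#' @inheritParams histogram_features
#' @return Named numeric vector of length 11.
#' @export
patch_features <- function(patch, levels = 8, distance = 1,
                           angles = c(0, 45, 90, 135), bins = 256) {
  c(glcm_features(patch, levels, distance, angles),
    histogram_features(patch, bins))
}

#' Feature-combination presets (table rows 1-9)
#'
#' The nine image-type combinations evaluated in the study tables:
#' rows 1-3 Raman only (1437 / 1655 / both), rows 4-6 autofluorescence
#' only, rows 7-8 both modalities of a single band, row 9 all four image
#' types.
#'
#' @param row Integer 1-9.
#' @return Character vector of image types among
#'   \code{c("raman_1437", "raman_1655", "af_1437", "af_1655")}.
#' @export
feature_preset <- function(row) {
  presets <- list(
    c("raman_1437"),
    c("raman_1655"),
    c("raman_1437", "raman_1655"),
    c("af_1437"),
    c("af_1655"),
    c("af_1437", "af_1655"),
    c("raman_1437", "af_1437"),
    c("raman_1655", "af_1655"),
    c("raman_1437", "raman_1655", "af_1437", "af_1655"))
  if (!row %in% 1:9) stop("preset row must be in 1..9")
  presets[[row]]
}

#' Separate every band image set of a phantom dataset
#'
#' Runs baseline decomposition of each sample's spectrum, derives the
#' spectral target ratio per band, and separates both band image sets,
#' yielding the four image types (Raman and scaled autofluorescence at
#' 1437 and 1655 cm^-1) per sample. With
#' \code{ratio_source = "truth"} the generator's ground-truth ratio is
#' used instead of the fitted one (useful to isolate image-domain errors).
#'
#' @param dataset A \code{phantom_dataset}.
#' @param ratio_source "spectrum" (fit the baseline) or "truth".
#' @return List of separated samples: each with \code{sample_id},
#'   \code{class_label}, \code{images} (named list of 4 matrices) and
#'   \code{separations}.
#' @export
separate_dataset <- function(dataset, ratio_source = c("spectrum", "truth")) {
  ratio_source <- match.arg(ratio_source)
  lapply(dataset, function(smp) {
    decomp <- if (ratio_source == "spectrum")
      subtract_baseline(smp$spectrum) else NULL
    seps <- lapply(smp$bands, function(bs) {
      r <- if (ratio_source == "truth") bs$ground_truth$target_ratio
           else spectral_target_ratio(decomp, bs$band_label)
      separate(bs, r)
    })
    images <- list(
      raman_1437 = seps[["1437"]]$raman_image,
      af_1437 = seps[["1437"]]$af_image_scaled,
      raman_1655 = seps[["1655"]]$raman_image,
      af_1655 = seps[["1655"]]$af_image_scaled)
    list(sample_id = smp$sample_id, class_label = smp$class_label,
         images = images, separations = seps,
         image_px = smp$image_px, field_cm = smp$field_cm)
  })
}

#' Build the patch-by-feature table
#'
#' Registers \code{n_patches} patches per sample (one transform set per
#' sample, shared across all selected image types so patches are spatially
#' matched across modalities) and computes the 11 features per patch per
#' image type. Columns are named {modality}_{band}_{feature}; tissue class
#' and sample id are attached as \code{label} and \code{group}.
#'
#' @param separated List of separated samples (see
#'   \code{\link{separate_dataset}}).
#' @param selection Character vector of image types, or a preset row via
#'   \code{\link{feature_preset}}. Default: all four types.
#' @param n_patches Patches per image (default 20).
#' @param patch_px Patch side (pixels); default maps the study's 1 cm^2
#'   patch area to pixels via the sample's field of view.
#' @param seed Integer seed for patch registration.
#' @param levels,distance,angles,bins Feature parameters (see
#'   \code{\link{glcm_features}}, \code{\link{histogram_features}}).
#' @return A data.frame of class \code{feature_table}: one row per
#'   (sample, patch), feature columns plus \code{label}, \code{group},
#'   \code{patch}.
#' @export
build_feature_table <- function(separated,
                                selection = feature_preset(9),
                                n_patches = 20, patch_px = NULL, seed = 1,
                                levels = 8, distance = 1,
                                angles = c(0, 45, 90, 135), bins = 256) {
  valid <- c("raman_1437", "raman_1655", "af_1437", "af_1655")
  if (!length(selection) || !all(selection %in% valid))
    stop("selection must be a nonempty subset of: ",
         paste(valid, collapse = ", "))
  rows <- list()
  for (si in seq_along(separated)) {
    smp <- separated[[si]]
    missing_types <- setdiff(selection, names(smp$images))
    if (length(missing_types))
      stop("sample ", smp$sample_id, " missing image type(s): ",
           paste(missing_types, collapse = ", "))
    dim_img <- dim(smp$images[[selection[1]]])
    pp <- patch_px
    if (is.null(pp))
      pp <- min(round(smp$image_px / smp$field_cm), min(dim_img))
    tr <- patch_transforms(dim_img, n_patches, pp,
                           seed = .sub_seed(seed, 500L + si))
    feats_by_type <- lapply(selection, function(ty) {
      ps <- extract_patches(smp$images[[ty]], patch_px = pp, transforms = tr)
      t(vapply(ps$patches, patch_features, numeric(11),
               levels = levels, distance = distance, angles = angles,
               bins = bins))
    })
    block <- do.call(cbind, lapply(seq_along(selection), function(j) {
      m <- feats_by_type[[j]]
      colnames(m) <- paste(selection[j], colnames(m), sep = "_")
      m
    }))
    df <- as.data.frame(block)
    df$label <- smp$class_label
    df$group <- smp$sample_id
    df$patch <- seq_len(n_patches)
    rows[[si]] <- df
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  if (anyNA(out)) stop("feature table contains missing values")
  class(out) <- c("feature_table", "data.frame")
  out
}

#' @export
print.feature_table <- function(x, ...) {
  nf <- sum(!names(x) %in% c("label", "group", "patch"))
  cat(sprintf("Feature table: %d patches x %d features (classes: %s)\n",
              nrow(x), nf, paste(unique(x$label), collapse = ", ")))
  invisible(x)
}
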