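#' Estimate the autofluorescence calibration constant k
#'
#' Finds the scalar k applied to the autofluorescence-position image B so
#' that, after subtracting k*B from the signal-position image A, the
#' image-domain ratio of mean autofluorescence to mean Raman intensity
#' matches the spectrally measured target ratio r:
#' mean(k*B) / mean(A - k*B) = r. The unique solution is the closed form
#' k = r * mean(A) / (mean(B) * (1 + r)); an iterative bisection solver
#' (the automated analogue of manually re-applying k until the ratios
#' match) is used as a cross-check and must agree within \code{tol}.
#'
#' @param image_set A \code{\link{band_image_set}}.
#' @param target_ratio Spectral AF/Raman ratio r > 0 (see
#'   \code{\link{spectral_target_ratio}}).
#' @param mask Optional logical matrix restricting the means to a region
#'   of interest; default uses the full frame.
#' @param tol Maximum tolerated relative disagreement between the closed
#'   form and the bisection estimate.
#' @return The estimated k (scalar, > 0).
#' @export
estimate_k <- function(image_set, target_ratio, mask = NULL, tol = 1e-6) {
  stopifnot(inherits(image_set, "band_image_set"))
  if (!is.finite(target_ratio) || target_ratio <= 0)
    stop("target_ratio must be a positive number")
  a <- image_set$signal_image
  b <- image_set$af_image
  if (!is.null(mask)) {
    if (!identical(dim(mask), dim(a))) stop("mask shape mismatch")
    a <- a[mask]; b <- b[mask]
  }
  ma <- mean(a); mb <- mean(b)
  if (mb <= 0) stop("mean of the AF-position image must be positive")
  k <- target_ratio * ma / (mb * (1 + target_ratio))
  if (ma - k * mb <= 0)
    stop("target ratio inconsistent with images: mean Raman would be <= 0")
  kb <- .estimate_k_bisection(ma, mb, target_ratio)
  if (abs(kb - k) / k > tol)
    stop("closed-form and bisection k estimates disagree: ",
         format(k, digits = 10), " vs ", format(kb, digits = 10))
  k
}

# bisection on g(k) = mean(k B)/(mean(A) - k mean(B)) - r, increasing on
# (0, mean(A)/mean(B))
.estimate_k_bisection <- function(ma, mb, r, rel_tol = 1e-12,
                                  max_iter = 200) {
  lo <- 0
  hi <- ma / mb * (1 - 1e-12)
  g <- function(k) k * mb / (ma - k * mb) - r
  for (i in seq_len(max_iter)) {
    mid <- (lo + hi) / 2
    if (g(mid) > 0) hi <- mid else lo <- mid
    if ((hi - lo) <= rel_tol * max(hi, 1e-300)) break
  }
  (lo + hi) / 2
}

#' Separate a Raman band image from its autofluorescence background
#'
#' Estimates k (see \code{\link{estimate_k}}), scales the
#' autofluorescence-position image, and subtracts it from the
#' signal-position image. Negative pixels of the difference are clamped to
#' zero (Raman intensity is physically nonnegative) and the clamped
#' fraction is reported; the achieved ratio is recomputed from the
#' unclamped means, so intensity is conserved before clamping:
#' A = raman_unclamped + k*B exactly.
#'
#' @inheritParams estimate_k
#' @param ratio_tol Maximum tolerated relative mismatch between the
#'   achieved and target ratios (warning beyond it).
#' @return An object of class \code{separation_result} with elements
#'   \code{k}, \code{raman_image}, \code{af_image_scaled},
#'   \code{achieved_ratio}, \code{target_ratio}, \code{clamped_fraction},
#'   \code{iterations}, plus band/sample metadata.
#' @export
separate <- function(image_set, target_ratio, mask = NULL, tol = 1e-6,
                     ratio_tol = 1e-3) {
  k <- estimate_k(image_set, target_ratio, mask = mask, tol = tol)
  a <- image_set$signal_image
  b <- image_set$af_image
  af_scaled <- k * b
  raman_unclamped <- a - af_scaled
  achieved <- mean(af_scaled) / mean(raman_unclamped)
  if (abs(achieved - target_ratio) / target_ratio > ratio_tol)
    warning("achieved AF/Raman ratio deviates from target by more than ",
            ratio_tol)
  raman <- pmax(raman_unclamped, 0)
  structure(
    list(k = k, raman_image = raman, af_image_scaled = af_scaled,
         raman_unclamped = raman_unclamped,
         achieved_ratio = achieved, target_ratio = target_ratio,
         clamped_fraction = mean(raman_unclamped < 0),
         iterations = 1L,
         band_label = image_set$band_label,
         sample_id = image_set$sample_id,
         class_label = image_set$class_label),
    class = "separation_result")
}

#' @export
print.separation_result <- function(x, ...) {
  cat(sprintf(
    "Band %g cm-1 separation: k = %.4f, achieved/target ratio = %.4g/%.4g, clamped %.2f%%\n",
    x$band_label, x$k, x$achieved_ratio, x$target_ratio,
    100 * x$clamped_fraction))
  invisible(x)
}

#' @export
summary.separation_result <- function(object, ...) {
  cat(sprintf("Raman band image separation at %g cm-1\n", object$band_label))
  if (!is.na(object$sample_id)) cat("  sample:", object$sample_id, "\n")
  cat(sprintf("  k = %.6g (target AF/Raman ratio %.4g, achieved %.4g)\n",
              object$k, object$target_ratio, object$achieved_ratio))
  cat(sprintf("  Raman image mean %.4g a.u.; scaled AF image mean %.4g a.u.\n",
              mean(object$raman_image), mean(object$af_image_scaled)))
  cat(sprintf("  clamped pixels: %.3f%%\n", 100 * object$clamped_fraction))
  invisible(object)
}

#' Coefficient of variation over a masked image region
#'
#' CV = sigma / mu over the masked pixels, with the population standard
#' deviation convention (divisor n).
#'
#' @param image 2-D intensity matrix.
#' @param mask Logical matrix selecting >= 2 pixels; default full frame.
#' @return Dimensionless CV.
#' @export
coefficient_of_variation <- function(image, mask = NULL) {
  v <- if (is.null(mask)) as.vector(image) else {
    if (!identical(dim(mask), dim(image))) stop("mask shape mismatch")
    image[mask]
  }
  if (length(v) < 2) stop("mask must select at least 2 pixels")
  mu <- mean(v)
  if (mu == 0) stop("zero mean over the masked region; CV undefined")
  sqrt(mean((v - mu)^2)) / mu
}

#' Lesion-to-surround CV contrast ratio
#'
#' Ratio of the coefficient of variation inside a lesion mask to that of
#' the surrounding region: a unit-free contrast parameter comparing the
#' relative intensity spread of regions with different means.
#'
#' @param image 2-D intensity matrix.
#' @param lesion_mask,surround_mask Disjoint logical masks, each selecting
#'   >= 2 pixels.
#' @return CV(lesion) / CV(surround).
#' @export
cv_ratio <- function(image, lesion_mask, surround_mask) {
  if (any(lesion_mask & surround_mask)) stop("masks must be disjoint")
  cv_l <- coefficient_of_variation(image, lesion_mask)
  cv_s <- coefficient_of_variation(image, surround_mask)
  if (cv_s == 0) stop("surround CV is zero; ratio undefined")
  cv_l / cv_s
}

#' Segment a lesion by 2-level k-means intensity clustering
#'
#' Clusters pixel intensities into two groups; the cluster with the higher
#' mean is labeled as lesion. Deterministic given the seed.
#'
#' @param image 2-D intensity matrix with >= 2 distinct values.
#' @param seed Integer seed.
#' @return Logical matrix (TRUE = lesion).
#' @export
segment_lesion <- function(image, seed = 1) {
  v <- as.vector(image)
  if (length(unique(v)) < 2) stop("constant image cannot be segmented")
  set.seed(seed)
  km <- stats::kmeans(v, centers = 2, nstart = 5, iter.max = 50)
  lesion_cluster <- which.max(km$centers)
  matrix(km$cluster == lesion_cluster, nrow(image), ncol(image))
}
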