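#' Separate autofluorescence baseline from Raman peaks
#'
#' Decomposes a measured spectrum into a smooth autofluorescence continuum
#' and a Raman component using an iterative peak-suppressing ("modified")
#' polynomial fit: fit a polynomial, clip intensities above the fit, and
#' refit until the working trace stops changing. The polynomial order is
#' chosen from \code{order_range} as the lowest order whose converged fit
#' removes close to the least total intensity mass (sum of positive
#' residuals; within 5% of the minimum) -- a good baseline clips only the
#' peaks, while an under- or over-fitting order also clips continuum
#' regions, and near-ties go to the lower order for parsimony. A final peak-masked refit (passes excluding points more than
#' 3, then 2, then 1.5 estimated noise sigma above the running fit)
#' removes the small downward bias the clipping leaves under broad peaks
#' while keeping enough continuum anchor points.
#'
#' The decomposition is exactly additive: \code{raman + autofluorescence}
#' reproduces the input intensities. The autofluorescence trace is clamped
#' at zero (fluorescence is nonnegative), with the difference absorbed by
#' the Raman component.
#'
#' @param spectrum A \code{\link{raman_spectrum}} covering 1200-1800 cm^-1.
#' @param order_range Integer vector of length 2; candidate polynomial
#'   orders, within [1, 20]. Default \code{c(9, 16)}.
#' @param tol Convergence tolerance: iteration stops when the maximum
#'   absolute change of the working trace drops below
#'   \code{tol * max(abs(intensities))}.
#' @param max_iter Iteration cap; non-convergence raises a warning, never a
#'   silent result.
#' @return An object of class \code{baseline_decomposition} with elements
#'   \code{wavenumbers}, \code{raman}, \code{autofluorescence},
#'   \code{polynomial_order}, \code{residual_norm}, \code{converged},
#'   \code{iterations}.
#' @export
subtract_baseline <- function(spectrum, order_range = c(9, 16),
                              tol = 1e-7, max_iter = 1000) {
  stopifnot(inherits(spectrum, "raman_spectrum"))
  wn <- spectrum$wavenumbers
  y <- spectrum$intensities
  if (wn[1] > 1200 || wn[length(wn)] < 1800)
    stop("spectrum must cover 1200-1800 cm-1")
  if (length(wn) < 50) stop("spectrum too short (< 50 samples)")
  order_range <- as.integer(round(order_range))
  if (length(order_range) != 2 || any(order_range < 1) || any(order_range > 20) ||
      order_range[1] > order_range[2])
    stop("order_range must lie within [1, 20]")

  x <- 2 * (wn - wn[1]) / (wn[length(wn)] - wn[1]) - 1
  scale_ref <- max(abs(y))
  # noise scale from second differences (robust to the smooth continuum)
  sigma_est <- stats::mad(diff(y, differences = 2)) / sqrt(6)
  orders <- seq(order_range[1], order_range[2])
  fits <- vector("list", length(orders))
  clip_mass <- numeric(length(orders))
  bases <- lapply(orders, function(o) cbind(1, stats::poly(x, o)))
  for (oi in seq_along(orders)) {
    basis <- bases[[oi]]
    qr_b <- qr(basis)
    yw <- y
    it <- 0L
    converged <- FALSE
    fit <- yw
    while (it < max_iter) {
      it <- it + 1L
      fit <- as.numeric(basis %*% qr.coef(qr_b, yw))
      yn <- pmin(yw, fit)
      if (max(abs(yn - yw)) < tol * scale_ref) { converged <- TRUE; yw <- yn; break }
      yw <- yn
    }
    fits[[oi]] <- list(af = fit, converged = converged, iterations = it,
                       residual_norm = sqrt(mean((yw - fit)^2)))
    clip_mass[oi] <- sum(pmax(y - fit, 0))
  }
  # lowest order whose clipped mass is within 5% of the best: near-ties go
  # to the smoother fit rather than to marginal high-order wiggle
  best <- which(clip_mass <= 1.05 * min(clip_mass))[1]
  sel <- fits[[best]]
  if (!sel$converged)
    warning("baseline fit (order ", orders[best], ") did not converge in ",
            max_iter, " iterations; residual norm ",
            format(sel$residual_norm, digits = 3))
  # peak-masked refit: fit only continuum-classified points, tightening
  # the peak threshold progressively; stop rather than fit a collapsed mask
  fit <- sel$af
  basis <- bases[[best]]
  for (mult in c(3, 2, 1.5)) {
    mask <- (y - fit) < mult * sigma_est
    if (sum(mask) < max(3 * (orders[best] + 1), 0.3 * length(y))) break
    fit <- as.numeric(basis %*%
                        qr.coef(qr(basis[mask, , drop = FALSE]), y[mask]))
  }
  af <- pmax(fit, 0)
  structure(
    list(wavenumbers = wn, raman = y - af, autofluorescence = af,
         polynomial_order = orders[best], residual_norm = sel$residual_norm,
         converged = sel$converged, iterations = sel$iterations,
         sample_id = spectrum$sample_id, class_label = spectrum$class_label),
    class = "baseline_decomposition")
}

#' @export
print.baseline_decomposition <- function(x, ...) {
  cat(sprintf(
    "Baseline decomposition: order %d, %d iterations%s, residual norm %.4g\n",
    x$polynomial_order, x$iterations,
    if (x$converged) "" else " (NOT converged)", x$residual_norm))
  invisible(x)
}

#' @export
plot.baseline_decomposition <- function(x, ...) {
  graphics::matplot(x$wavenumbers,
                    cbind(x$raman + x$autofluorescence, x$autofluorescence,
                          x$raman),
                    type = "l", lty = c(1, 2, 1),
                    col = c("grey40", "red", "blue"),
                    xlab = expression(paste("Raman shift (", cm^-1, ")")),
                    ylab = "Intensity (a.u.)", ...)
  graphics::legend("topright", c("input", "autofluorescence", "Raman"),
                   lty = c(1, 2, 1), col = c("grey40", "red", "blue"),
                   bty = "n")
  invisible(x)
}

#' Write / read a baseline decomposition as 3-column CSV
#'
#' Columns: wavenumber_cm-1, raman_au, autofluorescence_au.
#'
#' @param decomp A \code{baseline_decomposition}.
#' @param path Output CSV path.
#' @export
write_decomposition <- function(decomp, path) {
  df <- data.frame(`wavenumber_cm-1` = decomp$wavenumbers,
                   raman_au = decomp$raman,
                   autofluorescence_au = decomp$autofluorescence,
                   check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_decomposition
#' @export
read_decomposition <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  structure(
    list(wavenumbers = df[[1]], raman = df[[2]], autofluorescence = df[[3]],
         polynomial_order = NA_integer_, residual_norm = NA_real_,
         converged = NA, iterations = NA_integer_,
         sample_id = NA_character_, class_label = NA_character_),
    class = "baseline_decomposition")
}

#' Write / read a spectrum as 2-column CSV
#'
#' Columns: wavenumber_cm-1, intensity_au.
#'
#' @param spectrum A \code{raman_spectrum}.
#' @param path Output CSV path.
#' @export
write_spectrum <- function(spectrum, path) {
  df <- data.frame(`wavenumber_cm-1` = spectrum$wavenumbers,
                   intensity_au = spectrum$intensities, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_spectrum
#' @param sample_id,class_label Metadata attached on read.
#' @export
read_spectrum <- function(path, sample_id = NA_character_,
                          class_label = NA_character_) {
  df <- utils::read.csv(path, check.names = FALSE)
  raman_spectrum(df[[1]], df[[2]], sample_id = sample_id,
                 class_label = class_label)
}
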