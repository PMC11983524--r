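#' Construct a Raman spectrum object
#'
#' A spectrum is a sampled wavenumber/intensity trace with optional sample
#' metadata. Wavenumbers must be strictly increasing; intensities finite.
#'
#' @param wavenumbers Numeric vector of Raman shifts (cm^-1), strictly
#'   increasing.
#' @param intensities Numeric vector of intensities (a.u.), same length.
#' @param sample_id Optional sample identifier.
#' @param class_label Optional tissue class label (e.g. "MCT", "STS",
#'   "BENIGN").
#' @param replicate Optional replicate index.
#' @return An object of class \code{raman_spectrum}.
#' @export
raman_spectrum <- function(wavenumbers, intensities, sample_id = NA_character_,
                           class_label = NA_character_, replicate = 1L) {
  wavenumbers <- as.numeric(wavenumbers)
  intensities <- as.numeric(intensities)
  if (length(wavenumbers) != length(intensities))
    stop("wavenumbers and intensities must have the same length")
  if (any(!is.finite(wavenumbers)) || any(diff(wavenumbers) <= 0))
    stop("wavenumbers must be finite and strictly increasing")
  if (any(!is.finite(intensities)))
    stop("intensities must be finite")
  structure(
    list(wavenumbers = wavenumbers, intensities = intensities,
         sample_id = sample_id, class_label = class_label,
         replicate = as.integer(replicate)),
    class = "raman_spectrum")
}

#' @export
print.raman_spectrum <- function(x, ...) {
  cat(sprintf("Raman spectrum: %d samples, %.0f-%.0f cm-1\n",
              length(x$wavenumbers), min(x$wavenumbers), max(x$wavenumbers)))
  if (!is.na(x$sample_id)) cat("  sample:", x$sample_id, "\n")
  if (!is.na(x$class_label)) cat("  class: ", x$class_label, "\n")
  invisible(x)
}

#' @export
plot.raman_spectrum <- function(x, ...) {
  graphics::plot(x$wavenumbers, x$intensities, type = "l",
                 xlab = expression(paste("Raman shift (", cm^-1, ")")),
                 ylab = "Intensity (a.u.)", ...)
  invisible(x)
}

#' Calibrated filter passband windows
#'
#' The four effective passbands (50% transmittance limits, cm^-1) of the
#' two-filter compartment, one per filter-position label. Positions '0-R'
#' and 'R-R' belong to the 1437 cm^-1 band (signal and autofluorescence
#' windows); 'R-0' and '0-0' to the 1655 cm^-1 band. These are constants
#' of the instrument model.
#'
#' @param position One of "0-R", "R-R", "R-0", "0-0". If missing, the full
#'   table is returned.
#' @return A list with elements \code{band}, \code{position}, \code{lo},
#'   \code{hi}, or a data.frame of all four windows.
#' @export
band_window <- function(position) {
  tab <- data.frame(
    band = c(1437, 1437, 1655, 1655),
    position = c("0-R", "R-R", "R-0", "0-0"),
    lo = c(1365, 1358, 1625, 1651),
    hi = c(1455, 1418, 1715, 1716),
    role = c("signal", "af", "signal", "af"),
    stringsAsFactors = FALSE)
  if (missing(position)) return(tab)
  i <- match(position, tab$position)
  if (is.na(i)) stop("unknown filter position: ", position)
  as.list(tab[i, ])
}

#' Signal / autofluorescence window pair for a band
#'
#' @param band 1437 or 1655.
#' @return List with \code{signal} and \code{af} window lists.
#' @export
band_window_pair <- function(band) {
  band <- as.numeric(band)
  if (band == 1437) list(signal = band_window("0-R"), af = band_window("R-R"))
  else if (band == 1655) list(signal = band_window("R-0"), af = band_window("0-0"))
  else stop("band must be 1437 or 1655")
}

#' Trapezoidal band integral of an intensity trace
#'
#' Integrates an intensity trace over a passband window using the
#' trapezoidal rule, with linear interpolation at the window edges.
#'
#' @param wavenumbers Strictly increasing grid (cm^-1).
#' @param intensities Intensity trace on that grid.
#' @param window A window list with \code{lo}/\code{hi} (see
#'   \code{\link{band_window}}), or a numeric length-2 vector.
#' @return The integral (a.u. x cm^-1).
#' @export
band_integral <- function(wavenumbers, intensities, window) {
  if (is.numeric(window) && length(window) == 2)
    window <- list(lo = window[1], hi = window[2], position = "custom")
  lo <- window$lo; hi <- window$hi
  if (lo >= hi) stop("window lo must be < hi")
  wn <- wavenumbers
  if (hi <= wn[1] || lo >= wn[length(wn)])
    stop("window '", window$position, "' (", lo, "-", hi,
         " cm-1) does not overlap the spectrum axis")
  lo <- max(lo, wn[1]); hi <- min(hi, wn[length(wn)])
  inside <- wn > lo & wn < hi
  xs <- c(lo, wn[inside], hi)
  ys <- c(stats::approx(wn, intensities, xout = lo)$y,
          intensities[inside],
          stats::approx(wn, intensities, xout = hi)$y)
  sum(diff(xs) * (ys[-1] + ys[-length(ys)]) / 2)
}

#' Autofluorescence-to-Raman intensity ratio at a band center
#'
#' Reads the autofluorescence and Raman components of a baseline
#' decomposition at the grid sample nearest to \code{center} and returns
#' their ratio. This is the point-wise spectral ratio used to compare
#' residual autofluorescence strength between tissue groups.
#'
#' @param decomp A \code{baseline_decomposition} (see
#'   \code{\link{subtract_baseline}}).
#' @param center Band center (cm^-1).
#' @return Dimensionless ratio AF / Raman.
#' @export
af_raman_ratio <- function(decomp, center) {
  stopifnot(inherits(decomp, "baseline_decomposition"))
  wn <- decomp$wavenumbers
  if (center < wn[1] || center > wn[length(wn)])
    stop("center outside decomposition span")
  i <- which.min(abs(wn - center))
  r <- decomp$raman[i]
  if (r <= 0)
    stop("Raman intensity at ", center, " cm-1 is not positive; ratio undefined")
  decomp$autofluorescence[i] / r
}

#' Spectral target ratio for image separation
#'
#' Image separation is guided by the spectrally measured ratio of
#' autofluorescence to Raman intensity integrated over the band's signal
#' window. This is the target the image-domain mean-intensity ratio is
#' matched to when estimating the calibration constant k.
#'
#' @param decomp A \code{baseline_decomposition}.
#' @param band 1437 or 1655.
#' @return Dimensionless ratio of band integrals (AF / Raman) over the
#'   signal window.
#' @export
spectral_target_ratio <- function(decomp, band) {
  stopifnot(inherits(decomp, "baseline_decomposition"))
  win <- band_window_pair(band)$signal
  af <- band_integral(decomp$wavenumbers, decomp$autofluorescence, win)
  rm <- band_integral(decomp$wavenumbers, decomp$raman, win)
  if (rm <= 0) stop("Raman band integral not positive over signal window")
  af / rm
}

#' Convert a Raman shift to an absolute emission wavelength
#'
#' For Stokes scattering under excitation at \code{excitation} nm, a Raman
#' shift of \code{shift} cm^-1 is emitted at
#' 1e7 / (1e7/excitation - shift) nm.
#'
#' @param excitation Excitation wavelength (nm), > 0.
#' @param shift Raman shift (cm^-1); must be below the excitation
#'   wavenumber 1e7/excitation.
#' @return Emission wavelength (nm).
#' @examples
#' raman_shift_to_wavelength(785, 1437)  # ~884.8 nm
#' @export
raman_shift_to_wavelength <- function(excitation, shift) {
  if (any(excitation <= 0)) stop("excitation must be positive")
  nu0 <- 1e7 / excitation
  if (any(shift >= nu0)) stop("shift must be below the excitation wavenumber")
  1e7 / (nu0 - shift)
}
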