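#' Write a 2-D intensity image as 16-bit grayscale TIFF
#'
#' Integer-valued images within [0, 65535] are stored losslessly.
#' Float-valued images are linearly mapped to the 16-bit range and the
#' mapping (offset/scale) is stored in a JSON sidecar
#' (\code{<path>.json}), bounding the round-trip error by half a code
#' step, i.e. at most 1/65535 of the intensity range.
#'
#' @param image 2-D numeric matrix.
#' @param path Output .tiff path.
#' @return The path, invisibly.
#' @export
write_image <- function(image, path) {
  if (length(dim(image)) != 2) stop("image must be a 2-D matrix")
  if (any(!is.finite(image))) stop("image must be finite")
  lo <- min(image); hi <- max(image)
  integral <- all(image == round(image)) && lo >= 0 && hi <= 65535
  sidecar <- paste0(path, ".json")
  if (integral) {
    code <- image
    if (file.exists(sidecar)) unlink(sidecar)
  } else {
    rng <- if (hi > lo) hi - lo else 1
    code <- round((image - lo) / rng * 65535)
    jsonlite::write_json(list(encoding = "linear16", offset = lo,
                              scale = rng / 65535),
                         sidecar, auto_unbox = TRUE, digits = NA)
  }
  tiff::writeTIFF(code / 65535, path, bits.per.sample = 16,
                  compression = "none")
  invisible(path)
}

#' Read a grayscale TIFF written by \code{\link{write_image}}
#'
#' Applies the JSON sidecar mapping when present. Multi-channel images
#' are rejected: this pipeline works on single-channel intensity data.
#'
#' @param path .tiff path.
#' @return 2-D numeric matrix.
#' @export
read_image <- function(path) {
  img <- tiff::readTIFF(path, as.is = TRUE)
  if (length(dim(img)) != 2)
    stop("only single-channel grayscale TIFF is supported, got ",
         length(dim(img)), " dimensions in ", path)
  code <- img * 1.0
  sidecar <- paste0(path, ".json")
  if (file.exists(sidecar)) {
    sc <- jsonlite::read_json(sidecar)
    code <- code * sc$scale + sc$offset
  }
  code
}

#' Write a phantom sample to disk
#'
#' Band images as 16-bit TIFF named {sample_id}_{band}_{position}.tiff,
#' the spectrum as 2-column CSV, and the ground truth (true k, gain,
#' band integrals, spectral decomposition) as a JSON sidecar.
#'
#' @param sample A \code{phantom_sample}.
#' @param dir Output directory (created if needed).
#' @return The sample directory, invisibly.
#' @export
write_phantom_sample <- function(sample, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  sid <- sample$sample_id
  write_spectrum(sample$spectrum, file.path(dir,
                                            paste0(sid, "_spectrum.csv")))
  gt <- list(sample_id = sid, class_label = sample$class_label,
             image_px = sample$image_px, field_cm = sample$field_cm,
             spectrum_truth = sample$spectrum$ground_truth, bands = list())
  for (b in names(sample$bands)) {
    bs <- sample$bands[[b]]
    write_image(bs$signal_image,
                file.path(dir, sprintf("%s_%s_%s.tiff", sid, b,
                                       bs$signal_position)))
    write_image(bs$af_image,
                file.path(dir, sprintf("%s_%s_%s.tiff", sid, b,
                                       bs$af_position)))
    g <- bs$ground_truth
    gt$bands[[b]] <- list(k_true = g$k_true, gain = g$gain,
                          integral_raman = g$integral_raman,
                          integral_af_signal = g$integral_af_signal,
                          integral_af_af = g$integral_af_af,
                          target_ratio = g$target_ratio)
  }
  jsonlite::write_json(gt, file.path(dir, paste0(sid, "_truth.json")),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read a phantom sample directory back into a reduced sample object
#'
#' Reconstructs the spectrum and band image sets (with the scalar ground
#' truth from the JSON sidecar; the noise-free truth images are not
#' persisted).
#'
#' @param dir Sample directory.
#' @param sample_id Sample identifier (file name prefix).
#' @return A list shaped like a \code{phantom_sample}.
#' @export
read_phantom_sample <- function(dir, sample_id) {
  gt <- jsonlite::read_json(file.path(dir, paste0(sample_id, "_truth.json")),
                            simplifyVector = TRUE)
  sp <- read_spectrum(file.path(dir, paste0(sample_id, "_spectrum.csv")),
                      sample_id = sample_id, class_label = gt$class_label)
  if (!is.null(gt$spectrum_truth))
    sp$ground_truth <- list(
      raman = as.numeric(gt$spectrum_truth$raman),
      autofluorescence = as.numeric(gt$spectrum_truth$autofluorescence))
  bands <- list()
  for (b in c("1437", "1655")) {
    wins <- band_window_pair(as.numeric(b))
    sig <- read_image(file.path(dir, sprintf("%s_%s_%s.tiff", sample_id, b,
                                             wins$signal$position)))
    af <- read_image(file.path(dir, sprintf("%s_%s_%s.tiff", sample_id, b,
                                            wins$af$position)))
    bands[[b]] <- band_image_set(as.numeric(b), sig, af,
                                 sample_id = sample_id,
                                 class_label = gt$class_label,
                                 ground_truth = as.list(gt$bands[[b]]))
  }
  structure(list(sample_id = sample_id, class_label = gt$class_label,
                 spectrum = sp, bands = bands,
                 image_px = gt$image_px, field_cm = gt$field_cm),
            class = "phantom_sample")
}
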