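#' Default pipeline configuration
#'
#' The full set of knobs of the end-to-end pipeline: global seed, phantom
#' scale and class-effect strength, the target-ratio source, patch
#' registration, texture-feature parameters, and the evaluation grid.
#' The configuration round-trips through YAML and is hashed into every
#' run manifest.
#'
#' @return A named list of class \code{pipeline_config}.
#' @export
default_config <- function() {
  structure(list(
    seed = 1L,
    n_per_class = 14L,
    image_px = 256L,
    field_cm = 1.4,
    axis = list(from = 1200, to = 1800, by = 1),
    class_separation = 1,
    ratio_source = "spectrum",
    separation_tol = 1e-3,
    patches = list(n = 20L, patch_cm = 1),
    features = list(glcm_levels = 8L, glcm_distance = 1L,
                    glcm_angles = c(0L, 45L, 90L, 135L),
                    hist_bins = 256L),
    evaluation = list(
      comparisons = list(c("MCT", "STS"), c("MCT", "BENIGN"),
                         c("STS", "BENIGN")),
      presets = 1:9,
      classifiers = c("LDA", "SVM", "NB", "DT"),
      n_splits = 10L, train_fraction = 0.9, group_aware = FALSE)),
    class = "pipeline_config")
}

.check_keys <- function(cfg, template, path = "") {
  unknown <- setdiff(names(cfg), names(template))
  if (length(unknown))
    stop("unknown config key(s): ",
         paste0(path, unknown, collapse = ", "))
  for (k in names(cfg)) {
    if (is.list(template[[k]]) && !is.null(names(template[[k]])) &&
        is.list(cfg[[k]]))
      .check_keys(cfg[[k]], template[[k]], paste0(path, k, "."))
  }
  invisible(TRUE)
}

#' Validate and complete a pipeline configuration
#'
#' Unknown keys are rejected; missing keys are filled from
#' \code{\link{default_config}}.
#'
#' @param cfg A (partial) configuration list.
#' @return A complete \code{pipeline_config}.
#' @export
validate_config <- function(cfg) {
  template <- default_config()
  .check_keys(cfg, template)
  merge2 <- function(tmpl, x) {
    for (k in names(x)) {
      if (is.list(tmpl[[k]]) && !is.null(names(tmpl[[k]])) && is.list(x[[k]]))
        tmpl[[k]] <- merge2(tmpl[[k]], x[[k]])
      else tmpl[[k]] <- x[[k]]
    }
    tmpl
  }
  out <- merge2(unclass(template), unclass(cfg))
  if (out$n_per_class < 1) stop("n_per_class must be >= 1")
  if (!out$ratio_source %in% c("spectrum", "truth"))
    stop("ratio_source must be 'spectrum' or 'truth'")
  ev <- out$evaluation
  if (ev$train_fraction <= 0 || ev$train_fraction >= 1)
    stop("train_fraction must lie in (0, 1)")
  if (any(!unlist(ev$presets) %in% 1:9)) stop("presets must be in 1..9")
  if (any(!unlist(ev$classifiers) %in% c("LDA", "SVM", "NB", "DT")))
    stop("unknown classifier in config")
  structure(out, class = "pipeline_config")
}

#' Read / write a configuration as YAML
#'
#' @param path YAML file path.
#' @export
read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  cfg$evaluation$comparisons <- lapply(cfg$evaluation$comparisons, unlist)
  validate_config(cfg)
}

#' @rdname read_config
#' @param cfg A \code{pipeline_config}.
#' @export
write_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' Stable 32-bit FNV-1a hash of a configuration
#'
#' Hashes the canonical YAML serialization; recorded in every run
#' manifest so outputs can be traced to the exact configuration.
#'
#' @param cfg A \code{pipeline_config}.
#' @return 8-character hex string.
#' @export
config_hash <- function(cfg) {
  bytes <- as.integer(charToRaw(yaml::as.yaml(unclass(cfg))))
  h <- 2166136261
  for (b in bytes) {
    low <- h %% 256
    h <- h - low + bitwXor(as.integer(low), b)
    # 32-bit modular multiply by the FNV prime, split to keep exactness
    hi <- h %/% 65536
    lo <- h %% 65536
    h <- (lo * 16777619 + ((hi * 16777619) %% 65536) * 65536) %% 4294967296
  }
  paste0(sprintf("%04x", h %/% 65536), sprintf("%04x", h %% 65536))
}
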