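.axis_from_config <- function(cfg) seq(cfg$axis$from, cfg$axis$to,
                                       by = cfg$axis$by)

.patch_px_from_config <- function(cfg) {
  min(as.integer(round(cfg$image_px / cfg$field_cm * cfg$patches$patch_cm)),
      cfg$image_px)
}

#' Simulation stage: write a phantom dataset to disk
#'
#' @param cfg A \code{pipeline_config}.
#' @param out_dir Output directory; one subdirectory per sample plus an
#'   index JSON.
#' @return Invisibly, the sample index.
#' @export
pipeline_simulate <- function(cfg, out_dir) {
  cfg <- validate_config(cfg)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  ds <- generate_dataset(cfg$n_per_class,
                         phantom_class_table(cfg$class_separation),
                         seed = cfg$seed, image_px = cfg$image_px,
                         field_cm = cfg$field_cm,
                         axis = .axis_from_config(cfg))
  index <- data.frame(sample_id = names(ds),
                      class_label = vapply(ds, `[[`, "", "class_label"))
  for (sid in names(ds))
    write_phantom_sample(ds[[sid]], file.path(out_dir, sid))
  jsonlite::write_json(index, file.path(out_dir, "samples_index.json"),
                       auto_unbox = FALSE, digits = NA)
  invisible(index)
}

.read_sample_index <- function(dir) {
  p <- file.path(dir, "samples_index.json")
  if (!file.exists(p))
    stop("no samples_index.json under ", dir,
         "; expected the output of the simulate stage")
  jsonlite::read_json(p, simplifyVector = TRUE)
}

#' Separation stage: baseline fit and Raman/AF image separation
#'
#' Reads each sample written by the simulate stage, decomposes its
#' spectrum, derives per-band spectral target ratios, separates both band
#' image sets, and writes raman_{band}.tiff / af_{band}.tiff (with JSON
#' scale sidecars), the decomposition CSV, and a per-sample separation
#' report (k, ratios, clamped fraction).
#'
#' @param in_dir Directory written by \code{\link{pipeline_simulate}}.
#' @param out_dir Output directory.
#' @param cfg A \code{pipeline_config}.
#' @return Invisibly, a data.frame of separation reports.
#' @export
pipeline_separate <- function(in_dir, out_dir, cfg) {
  cfg <- validate_config(cfg)
  index <- .read_sample_index(in_dir)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  reports <- list()
  for (i in seq_len(nrow(index))) {
    sid <- index$sample_id[i]
    smp <- read_phantom_sample(file.path(in_dir, sid), sid)
    sdir <- file.path(out_dir, sid)
    dir.create(sdir, recursive = TRUE, showWarnings = FALSE)
    decomp <- NULL
    if (cfg$ratio_source == "spectrum") {
      decomp <- subtract_baseline(smp$spectrum)
      write_decomposition(decomp, file.path(sdir,
                                            paste0(sid, "_decomposition.csv")))
    }
    rep_bands <- list()
    for (b in names(smp$bands)) {
      bs <- smp$bands[[b]]
      r <- if (cfg$ratio_source == "truth") bs$ground_truth$target_ratio
           else spectral_target_ratio(decomp, bs$band_label)
      sep <- separate(bs, r, ratio_tol = cfg$separation_tol)
      write_image(sep$raman_image, file.path(sdir,
                                             sprintf("raman_%s.tiff", b)))
      write_image(sep$af_image_scaled, file.path(sdir,
                                                 sprintf("af_%s.tiff", b)))
      rep_bands[[b]] <- list(k = sep$k, target_ratio = sep$target_ratio,
                             achieved_ratio = sep$achieved_ratio,
                             clamped_fraction = sep$clamped_fraction)
      reports[[length(reports) + 1L]] <- data.frame(
        sample_id = sid, class_label = smp$class_label, band = as.numeric(b),
        k = sep$k, target_ratio = sep$target_ratio,
        clamped_fraction = sep$clamped_fraction)
    }
    jsonlite::write_json(
      list(sample_id = sid, class_label = smp$class_label,
           image_px = smp$image_px, field_cm = smp$field_cm,
           ratio_source = cfg$ratio_source, bands = rep_bands),
      file.path(sdir, "separation_report.json"),
      auto_unbox = TRUE, digits = NA)
  }
  rep_df <- do.call(rbind, reports)
  utils::write.csv(rep_df, file.path(out_dir, "separation_reports.csv"),
                   row.names = FALSE)
  jsonlite::write_json(index, file.path(out_dir, "samples_index.json"),
                       auto_unbox = FALSE, digits = NA)
  invisible(rep_df)
}

#' Feature stage: patch registration and texture features
#'
#' Reads the separated images and writes the full patch-by-feature table
#' (all four image types) as features.csv.
#'
#' @param in_dir Directory written by \code{\link{pipeline_separate}}.
#' @param out_dir Output directory.
#' @param cfg A \code{pipeline_config}.
#' @return Invisibly, the feature table.
#' @export
pipeline_features <- function(in_dir, out_dir, cfg) {
  cfg <- validate_config(cfg)
  index <- .read_sample_index(in_dir)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  separated <- lapply(seq_len(nrow(index)), function(i) {
    sid <- index$sample_id[i]
    sdir <- file.path(in_dir, sid)
    rep <- jsonlite::read_json(file.path(sdir, "separation_report.json"),
                               simplifyVector = TRUE)
    list(sample_id = sid, class_label = rep$class_label,
         image_px = rep$image_px, field_cm = rep$field_cm,
         images = list(
           raman_1437 = read_image(file.path(sdir, "raman_1437.tiff")),
           af_1437 = read_image(file.path(sdir, "af_1437.tiff")),
           raman_1655 = read_image(file.path(sdir, "raman_1655.tiff")),
           af_1655 = read_image(file.path(sdir, "af_1655.tiff"))))
  })
  ft <- build_feature_table(
    separated, selection = feature_preset(9),
    n_patches = cfg$patches$n, patch_px = .patch_px_from_config(cfg),
    seed = cfg$seed, levels = cfg$features$glcm_levels,
    distance = cfg$features$glcm_distance,
    angles = cfg$features$glcm_angles, bins = cfg$features$hist_bins)
  utils::write.csv(ft, file.path(out_dir, "features.csv"), row.names = FALSE)
  invisible(ft)
}

#' Classification stage: the evaluation grid
#'
#' Reads features.csv and writes the long-format results table
#' (comparison, preset, classifier, cumulated confusion counts, metrics)
#' as results.csv.
#'
#' @param in_dir Directory containing features.csv.
#' @param out_dir Output directory.
#' @param cfg A \code{pipeline_config}.
#' @return Invisibly, the results grid.
#' @export
pipeline_classify <- function(in_dir, out_dir, cfg) {
  cfg <- validate_config(cfg)
  fpath <- file.path(in_dir, "features.csv")
  if (!file.exists(fpath))
    stop("no features.csv under ", in_dir,
         "; expected the output of the features stage")
  ft <- utils::read.csv(fpath, check.names = FALSE)
  class(ft) <- c("feature_table", "data.frame")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  ev <- cfg$evaluation
  grid <- run_comparison_grid(ft, comparisons = ev$comparisons,
                              presets = unlist(ev$presets),
                              classifiers = unlist(ev$classifiers),
                              seed = cfg$seed, n_splits = ev$n_splits,
                              train_fraction = ev$train_fraction,
                              group_aware = ev$group_aware)
  utils::write.csv(grid, file.path(out_dir, "results.csv"),
                   row.names = FALSE)
  invisible(grid)
}

#' Report stage: summarize the evaluation grid
#'
#' @param in_dir Directory containing results.csv.
#' @param out_dir Output directory for report.json.
#' @return Invisibly, the summary list.
#' @export
pipeline_report <- function(in_dir, out_dir) {
  rpath <- file.path(in_dir, "results.csv")
  if (!file.exists(rpath))
    stop("no results.csv under ", in_dir,
         "; expected the output of the classify stage")
  grid <- utils::read.csv(rpath)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  best <- do.call(rbind, lapply(split(grid, grid$comparison), function(g)
    g[which.max(g$accuracy), c("comparison", "preset", "classifier",
                               "accuracy")]))
  summary <- list(n_cells = nrow(grid),
                  median_accuracy = stats::median(grid$accuracy),
                  best_by_comparison = best)
  jsonlite::write_json(summary, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(summary)
}

#' Run the full pipeline end-to-end
#'
#' simulate -> baseline/separate -> features -> classify -> report, each
#' stage reading the previous stage's on-disk outputs under
#' \code{out_dir}. A run manifest (config hash, seed, per-sample k and
#' clamped fractions, timestamps) is written on success; a failing stage
#' aborts with the stage named. Identical configuration and seed yield
#' byte-identical feature tables and results CSVs.
#'
#' @param cfg A \code{pipeline_config} (or partial list; completed via
#'   \code{\link{validate_config}}).
#' @param out_dir Run directory.
#' @return Invisibly, the manifest list.
#' @export
run_pipeline <- function(cfg = default_config(), out_dir) {
  cfg <- validate_config(cfg)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  t0 <- Sys.time()
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  dirs <- list(samples = file.path(out_dir, "samples"),
               separated = file.path(out_dir, "separated"),
               features = file.path(out_dir, "features"),
               results = file.path(out_dir, "results"))
  stage("simulate", pipeline_simulate(cfg, dirs$samples))
  reports <- stage("separate",
                   pipeline_separate(dirs$samples, dirs$separated, cfg))
  stage("features", pipeline_features(dirs$separated, dirs$features, cfg))
  stage("classify", pipeline_classify(dirs$features, dirs$results, cfg))
  stage("report", pipeline_report(dirs$results, dirs$results))
  manifest <- list(
    config_hash = config_hash(cfg), seed = cfg$seed,
    config = unclass(cfg),
    separation = reports,
    started = format(t0, "%Y-%m-%dT%H:%M:%S%z"),
    finished = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(manifest)
}
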