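.feature_cols <- function(table) setdiff(names(table),
                                         c("label", "group", "patch"))

.standardize_fit <- function(x) {
  ctr <- colMeans(x)
  scl <- apply(x, 2, stats::sd)
  scl[scl == 0 | !is.finite(scl)] <- 1
  list(center = ctr, scale = scl)
}

.standardize_apply <- function(x, st) {
  scale(x, center = st$center, scale = st$scale)
}

#' Train a binary tissue classifier
#'
#' Fits one of the four supervised classifiers on a feature table:
#' linear discriminant analysis (LDA, pooled covariance), support vector
#' machine (SVM, linear kernel, unit cost), Gaussian naive Bayes (NB), or
#' a decision tree (DT, Gini impurity, grown without depth restriction).
#' Features are standardized using training-set statistics only; the
#' statistics are stored in the model and applied at prediction time.
#'
#' @param table A \code{feature_table} with >= 2 classes and >= 2 rows per
#'   class.
#' @param kind One of "LDA", "SVM", "NB", "DT".
#' @param seed Integer seed (fitting is deterministic; the seed fixes any
#'   library-internal randomness).
#' @return An object of class \code{rb_classifier}.
#' @export
train_classifier <- function(table, kind = c("LDA", "SVM", "NB", "DT"),
                             seed = 1) {
  kind <- match.arg(kind)
  x <- as.matrix(table[, .feature_cols(table), drop = FALSE])
  if (any(!is.finite(x))) stop("non-finite feature values")
  y <- factor(table$label)
  if (nlevels(y) < 2) stop("training data contains a single class")
  if (any(tabulate(y) < 2)) stop("each class needs >= 2 training rows")
  st <- .standardize_fit(x)
  xs <- .standardize_apply(x, st)
  set.seed(seed)
  fit <- switch(
    kind,
    LDA = MASS::lda(xs, grouping = y),
    SVM = e1071::svm(xs, y, kernel = "linear", cost = 1, scale = FALSE),
    NB = e1071::naiveBayes(as.data.frame(xs), y),
    DT = {
      df <- as.data.frame(xs)
      df$.label <- y
      rpart::rpart(.label ~ ., data = df, method = "class",
                   parms = list(split = "gini"),
                   control = rpart::rpart.control(minsplit = 2, minbucket = 1,
                                                  cp = 0, xval = 0,
                                                  maxdepth = 30))
    })
  structure(list(kind = kind, fit = fit, standardize = st,
                 levels = levels(y), features = colnames(x)),
            class = "rb_classifier")
}

#' @export
predict.rb_classifier <- function(object, newdata, ...) {
  x <- as.matrix(newdata[, object$features, drop = FALSE])
  xs <- .standardize_apply(x, object$standardize)
  pred <- switch(
    object$kind,
    LDA = stats::predict(object$fit, xs)$class,
    SVM = stats::predict(object$fit, xs),
    NB = stats::predict(object$fit, as.data.frame(xs)),
    DT = {
      df <- as.data.frame(xs)
      stats::predict(object$fit, df, type = "class")
    })
  factor(as.character(pred), levels = object$levels)
}

#' @export
print.rb_classifier <- function(x, ...) {
  cat(sprintf("%s classifier on %d features (classes: %s)\n", x$kind,
              length(x$features), paste(x$levels, collapse = " vs ")))
  invisible(x)
}

#' Confusion matrix counts and derived metrics
#'
#' accuracy = (tp+tn)/total, sensitivity = tp/(tp+fn),
#' specificity = tn/(tn+fp), precision = tp/(tp+fp).
#'
#' @param truth,pred Factors with identical level sets.
#' @param positive The positive class label.
#' @return Named numeric vector (tp, fp, tn, fn).
#' @export
confusion_counts <- function(truth, pred, positive) {
  truth_pos <- truth == positive
  pred_pos <- pred == positive
  c(tp = sum(truth_pos & pred_pos), fp = sum(!truth_pos & pred_pos),
    tn = sum(!truth_pos & !pred_pos), fn = sum(truth_pos & !pred_pos))
}

#' @rdname confusion_counts
#' @param counts Named vector with tp, fp, tn, fn.
#' @export
confusion_metrics <- function(counts) {
  tp <- counts[["tp"]]; fp <- counts[["fp"]]
  tn <- counts[["tn"]]; fn <- counts[["fn"]]
  total <- tp + fp + tn + fn
  if (total == 0) stop("empty confusion matrix")
  div <- function(a, b) if (b == 0) NA_real_ else a / b
  c(accuracy = (tp + tn) / total,
    sensitivity = div(tp, tp + fn),
    specificity = div(tn, tn + fp),
    precision = div(tp, tp + fp))
}

.stratified_folds <- function(y, folds) {
  assign <- integer(length(y))
  for (cl in levels(y)) {
    idx <- sample(which(y == cl))
    assign[idx] <- rep_len(seq_len(folds), length(idx))
  }
  assign
}

#' Resubstitution and stratified 10-fold cross-validated metrics
#'
#' Resubstitution (training data predicted by the model trained on it)
#' flags under-fitting; stratified k-fold cross-validation estimates
#' performance on unseen patches. Folds are deterministic given the seed.
#'
#' @inheritParams train_classifier
#' @param folds Number of CV folds (default 10).
#' @param positive Positive class; default the first factor level.
#' @return List with \code{resubstitution} and \code{cv} metric vectors
#'   plus the cumulated CV confusion counts.
#' @export
resubstitution_and_cv <- function(table, kind, seed = 1, folds = 10,
                                  positive = NULL) {
  y <- factor(table$label)
  if (nrow(table) < folds) stop("fewer rows than folds")
  if (is.null(positive)) positive <- levels(y)[1]
  model <- train_classifier(table, kind, seed = seed)
  resub <- confusion_metrics(confusion_counts(y, predict(model, table),
                                              positive))
  set.seed(.sub_seed(seed, 7L))
  assign <- .stratified_folds(y, folds)
  counts <- c(tp = 0, fp = 0, tn = 0, fn = 0)
  for (f in seq_len(folds)) {
    tr <- table[assign != f, , drop = FALSE]
    te <- table[assign == f, , drop = FALSE]
    if (!nrow(te)) next
    m <- train_classifier(tr, kind, seed = seed)
    counts <- counts + confusion_counts(factor(te$label, levels(y)),
                                        predict(m, te), positive)
  }
  list(resubstitution = resub, cv = confusion_metrics(counts),
       cv_counts = counts)
}

#' Repeated 90/10 holdout with cumulated confusion matrix
#'
#' Draws \code{n_splits} random stratified train/test splits (default 10
#' splits at 90% training), evaluates the classifier on each held-out set,
#' and cumulates the per-split confusion matrices elementwise into one
#' matrix from which accuracy, sensitivity, specificity and precision are
#' computed. The positive class is the first-listed class of the
#' comparison. With \code{group_aware = TRUE} splits are drawn at the
#' sample level instead of the patch level, so no sample contributes
#' patches to both training and test data.
#'
#' @inheritParams train_classifier
#' @param n_splits Number of splits (default 10).
#' @param train_fraction Training fraction (default 0.9).
#' @param positive Positive class; default first factor level.
#' @param group_aware Split by sample id rather than by patch.
#' @param max_redraws Re-draws allowed when a split yields a single-class
#'   training set.
#' @return An object of class \code{holdout_result}: cumulated counts,
#'   metrics, per-split counts, and the evaluation settings.
#' @export
repeated_holdout <- function(table, kind, seed = 1, n_splits = 10,
                             train_fraction = 0.9, positive = NULL,
                             group_aware = FALSE, max_redraws = 100) {
  stopifnot(train_fraction > 0, train_fraction < 1, n_splits >= 1)
  y <- factor(table$label)
  if (is.null(positive)) positive <- levels(y)[1]
  set.seed(.sub_seed(seed, 13L))
  per_split <- vector("list", n_splits)
  for (s in seq_len(n_splits)) {
    for (attempt in seq_len(max_redraws + 1)) {
      test_idx <- if (group_aware) {
        ids <- unique(table$group)
        id_class <- vapply(ids, function(g)
          as.character(y[match(g, table$group)]), "")
        test_ids <- unlist(lapply(levels(y), function(cl) {
          g <- ids[id_class == cl]
          sample(g, max(1, round((1 - train_fraction) * length(g))))
        }))
        which(table$group %in% test_ids)
      } else {
        unlist(lapply(levels(y), function(cl) {
          idx <- which(y == cl)
          sample(idx, max(1, round((1 - train_fraction) * length(idx))))
        }))
      }
      tr <- table[-test_idx, , drop = FALSE]
      if (length(unique(tr$label)) >= 2 && min(table(tr$label)) >= 2) break
      if (attempt > max_redraws)
        stop("could not draw a split with a two-class training set")
    }
    te <- table[test_idx, , drop = FALSE]
    m <- train_classifier(tr, kind, seed = .sub_seed(seed, 17L + s))
    per_split[[s]] <- confusion_counts(factor(te$label, levels(y)),
                                       predict(m, te), positive)
  }
  cumulated <- Reduce(`+`, per_split)
  structure(
    list(kind = kind, positive = positive, n_splits = n_splits,
         train_fraction = train_fraction, group_aware = group_aware,
         seed = seed, per_split = per_split, cumulated = cumulated,
         metrics = confusion_metrics(cumulated)),
    class = "holdout_result")
}

#' @export
print.holdout_result <- function(x, ...) {
  m <- x$metrics
  cat(sprintf(
    "%s, %d x %d%%/%d%% splits (positive: %s)%s\n",
    x$kind, x$n_splits, round(100 * x$train_fraction),
    round(100 * (1 - x$train_fraction)), x$positive,
    if (x$group_aware) ", sample-level splits" else ""))
  cat(sprintf("  cumulated tp=%d fp=%d tn=%d fn=%d\n",
              x$cumulated[["tp"]], x$cumulated[["fp"]],
              x$cumulated[["tn"]], x$cumulated[["fn"]]))
  cat(sprintf(
    "  accuracy %.4f | sensitivity %.4f | specificity %.4f | precision %.4f\n",
    m[["accuracy"]], m[["sensitivity"]], m[["specificity"]],
    m[["precision"]]))
  invisible(x)
}

#' Run the full comparison x preset x classifier evaluation grid
#'
#' For each pairwise tissue comparison, feature preset (table rows 1-9)
#' and classifier, runs the repeated-holdout protocol and collects the
#' cumulated confusion counts and metrics into a long-format table
#' mirroring the study tables' layout (3 comparisons x 9 presets x 4
#' classifiers = 108 cells by default). The positive class of each cell is
#' the first-listed class of its comparison.
#'
#' @param full_table Feature table containing all four image types (the
#'   presets select columns from it).
#' @param comparisons List of length-2 character vectors of class labels.
#' @param presets Integer preset rows (see \code{\link{feature_preset}}).
#' @param classifiers Character vector among LDA, SVM, NB, DT.
#' @param seed Integer seed.
#' @inheritParams repeated_holdout
#' @return data.frame of class \code{evaluation_grid} with columns
#'   comparison, preset, classifier, tp, fp, tn, fn, accuracy,
#'   sensitivity, specificity, precision.
#' @export
run_comparison_grid <- function(full_table,
                                comparisons = list(c("MCT", "STS"),
                                                   c("MCT", "BENIGN"),
                                                   c("STS", "BENIGN")),
                                presets = 1:9,
                                classifiers = c("LDA", "SVM", "NB", "DT"),
                                seed = 1, n_splits = 10,
                                train_fraction = 0.9, group_aware = FALSE) {
  meta <- c("label", "group", "patch")
  out <- list()
  cell <- 0L
  for (ci in seq_along(comparisons)) {
    comp <- comparisons[[ci]]
    sub_all <- full_table[full_table$label %in% comp, , drop = FALSE]
    sub_all$label <- factor(sub_all$label, levels = comp)
    for (pr in presets) {
      types <- feature_preset(pr)
      cols <- unlist(lapply(types, function(ty)
        grep(paste0("^", ty, "_"), names(full_table), value = TRUE)))
      if (!length(cols))
        stop("feature table lacks columns for preset row ", pr)
      tab <- sub_all[, c(cols, meta), drop = FALSE]
      class(tab) <- c("feature_table", "data.frame")
      for (kind in classifiers) {
        cell <- cell + 1L
        res <- repeated_holdout(tab, kind,
                                seed = .sub_seed(seed, 1000L + cell),
                                n_splits = n_splits,
                                train_fraction = train_fraction,
                                positive = comp[1],
                                group_aware = group_aware)
        out[[cell]] <- data.frame(
          comparison = paste(comp, collapse = "-vs-"),
          preset = pr, classifier = kind,
          tp = res$cumulated[["tp"]], fp = res$cumulated[["fp"]],
          tn = res$cumulated[["tn"]], fn = res$cumulated[["fn"]],
          accuracy = res$metrics[["accuracy"]],
          sensitivity = res$metrics[["sensitivity"]],
          specificity = res$metrics[["specificity"]],
          precision = res$metrics[["precision"]])
      }
    }
  }
  grid <- do.call(rbind, out)
  rownames(grid) <- NULL
  class(grid) <- c("evaluation_grid", "data.frame")
  grid
}

#' Group comparison statistics
#'
#' Two-sided tests of group differences: pairwise unpaired Mann-Whitney
#' (Wilcoxon rank-sum) tests, or a one-way ANOVA over all groups. Used to
#' compare the distributions of calibration constants k and of
#' autofluorescence-to-Raman spectral ratios between tissue groups.
#'
#' @param values Numeric vector.
#' @param groups Factor or character vector of group labels.
#' @param test "mann_whitney" or "anova".
#' @return data.frame with columns comparison, statistic, p_value.
#' @export
group_stats <- function(values, groups, test = c("mann_whitney", "anova")) {
  test <- match.arg(test)
  groups <- factor(groups)
  if (nlevels(groups) < 2) stop("need at least two groups")
  sizes <- table(groups)
  if (any(sizes == 0)) stop("empty group")
  if (any(sizes < 3)) stop("each group needs at least 3 values")
  if (test == "anova") {
    fit <- stats::aov(values ~ groups)
    s <- summary(fit)[[1]]
    return(data.frame(comparison = paste(levels(groups), collapse = "-"),
                      statistic = s$`F value`[1], p_value = s$`Pr(>F)`[1]))
  }
  pairs <- utils::combn(levels(groups), 2, simplify = FALSE)
  do.call(rbind, lapply(pairs, function(pp) {
    wt <- stats::wilcox.test(values[groups == pp[1]], values[groups == pp[2]],
                             exact = FALSE)
    data.frame(comparison = paste(pp, collapse = "-"),
               statistic = unname(wt$statistic), p_value = wt$p.value)
  }))
}
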