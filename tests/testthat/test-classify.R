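test_that("separable data is classified perfectly at resubstitution", {
  tab <- separable_table()
  for (kind in c("SVM", "DT")) {
    m <- train_classifier(tab, kind)
    acc <- mean(predict(m, tab) == tab$label)
    expect_equal(acc, 1.0, label = paste(kind, "resubstitution"))
  }
  res <- resubstitution_and_cv(tab, "SVM", seed = 1)
  expect_equal(res$resubstitution[["accuracy"]], 1.0)
  expect_gte(res$cv[["accuracy"]], 0.95)
})

test_that("training rejects degenerate inputs", {
  tab <- separable_table()
  one <- tab[tab$label == "A", ]
  expect_error(train_classifier(one, "LDA"), "single class")
  tab$f1[1] <- NA
  expect_error(train_classifier(tab, "SVM"), "non-finite")
})

test_that("predictions are deterministic given data and seed", {
  tab <- separable_table(shift = 1.5, seed = 7)
  for (kind in c("LDA", "SVM", "NB", "DT")) {
    m1 <- train_classifier(tab, kind, seed = 5)
    m2 <- train_classifier(tab, kind, seed = 5)
    expect_identical(predict(m1, tab), predict(m2, tab), label = kind)
  }
})

test_that("permuted labels give chance-level cross-validation accuracy", {
  accs <- vapply(1:10, function(s) {
    tab <- separable_table(n_per_class = 60, shift = 6, seed = s)
    set.seed(s)
    tab$label <- sample(tab$label)
    resubstitution_and_cv(tab, "LDA", seed = s)$cv[["accuracy"]]
  }, 0)
  expect_gte(sum(accs >= 0.35 & accs <= 0.65), 8)
})

test_that("decision tree resubstitution dominates its CV accuracy", {
  tab <- separable_table(n_per_class = 40, shift = 0.8, seed = 3)
  res <- resubstitution_and_cv(tab, "DT", seed = 3)
  expect_gte(res$resubstitution[["accuracy"]], res$cv[["accuracy"]])
})

test_that("cross-validation requires at least as many rows as folds", {
  tab <- separable_table(n_per_class = 4)
  expect_error(resubstitution_and_cv(tab[1:9, ], "LDA", folds = 10),
               "fewer rows")
})

test_that("confusion metrics follow their definitions exactly", {
  m <- confusion_metrics(c(tp = 9, fn = 1, tn = 8, fp = 2))
  expect_equal(m[["accuracy"]], 0.85)
  expect_equal(m[["sensitivity"]], 0.90)
  expect_equal(m[["specificity"]], 0.80)
  expect_equal(m[["precision"]], 9 / 11, tolerance = 1e-6)
  expect_error(confusion_metrics(c(tp = 0, fp = 0, tn = 0, fn = 0)),
               "empty")
})

test_that("repeated holdout cumulates per-split confusion matrices", {
  tab <- separable_table(n_per_class = 30, shift = 2, seed = 11)
  res <- repeated_holdout(tab, "LDA", seed = 2)
  expect_length(res$per_split, 10)
  expect_equal(res$cumulated, Reduce(`+`, res$per_split))
  # cumulated total equals the sum of the 10 test-set sizes
  expect_equal(sum(res$cumulated), sum(vapply(res$per_split, sum, 0)))
  expect_equal(res$metrics, confusion_metrics(res$cumulated))
  # perfect classifier on separable data
  res2 <- repeated_holdout(separable_table(seed = 12), "SVM", seed = 2)
  expect_equal(unname(res2$metrics), rep(1, 4))
})

test_that("swapping the positive class swaps sensitivity and specificity", {
  tab <- separable_table(n_per_class = 30, shift = 1.2, seed = 13)
  ra <- repeated_holdout(tab, "NB", seed = 4, positive = "A")
  rb <- repeated_holdout(tab, "NB", seed = 4, positive = "B")
  expect_equal(ra$metrics[["sensitivity"]], rb$metrics[["specificity"]])
  expect_equal(ra$metrics[["specificity"]], rb$metrics[["sensitivity"]])
  expect_equal(ra$metrics[["accuracy"]], rb$metrics[["accuracy"]])
})

test_that("group-aware splits keep samples out of both sides", {
  tab <- separable_table(n_per_class = 6, shift = 3, seed = 14)
  tab <- tab[rep(seq_len(nrow(tab)), each = 5), ]  # 5 patches per sample
  tab$patch <- rep(1:5, 12)
  res <- repeated_holdout(tab, "LDA", seed = 5, group_aware = TRUE)
  expect_s3_class(res, "holdout_result")
  expect_true(res$group_aware)
  expect_equal(sum(res$cumulated), 10 * 2 * 5)  # 1 sample/class/split
})

test_that("the evaluation grid yields one cell per combination", {
  p <- quiet_params()
  ds <- generate_dataset(2, seed = 17, image_px = 48)
  sep <- separate_dataset(ds, ratio_source = "truth")
  ft <- build_feature_table(sep, n_patches = 5, patch_px = 24, seed = 1)
  grid <- suppressWarnings(
    run_comparison_grid(ft, presets = c(1, 7, 9),
                        classifiers = c("LDA", "DT"), seed = 1))
  expect_equal(nrow(grid), 3 * 3 * 2)
  expect_setequal(unique(grid$comparison),
                  c("MCT-vs-STS", "MCT-vs-BENIGN", "STS-vs-BENIGN"))
  # metric identities hold for every cell
  for (i in seq_len(nrow(grid))) {
    m <- confusion_metrics(c(tp = grid$tp[i], fp = grid$fp[i],
                             tn = grid$tn[i], fn = grid$fn[i]))
    expect_equal(grid$accuracy[i], m[["accuracy"]])
    expect_equal(grid$sensitivity[i], m[["sensitivity"]])
  }
})

test_that("group statistics behave for null and strong effects", {
  x <- rep(c(1, 2, 3, 4, 5), 2)
  g <- rep(c("a", "b"), each = 5)
  res <- group_stats(x, g, test = "mann_whitney")
  expect_gt(res$p_value, 0.99)
  hits <- 0
  for (s in 1:20) {
    set.seed(s)
    v <- c(rnorm(14), rnorm(14, mean = 5))
    gg <- rep(c("a", "b"), each = 14)
    if (group_stats(v, gg, "mann_whitney")$p_value < 0.001) hits <- hits + 1
  }
  expect_gte(hits, 19)
  av <- group_stats(c(rnorm(10), rnorm(10, 8), rnorm(10)),
                    rep(c("a", "b", "c"), each = 10), test = "anova")
  expect_lt(av$p_value, 0.01)
  expect_error(group_stats(1:5, c("a", "a", "a", "a", "a")), "two groups")
  expect_error(group_stats(1:5, c("a", "a", "a", "b", "b")), "at least 3")
})
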