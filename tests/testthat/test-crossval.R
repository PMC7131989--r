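# Splitting schemes and benchmark orchestration.

test_that("monte carlo splits have the expected sizes and partition the samples", {
  labels <- setNames(rep(c("a", "b", "b"), 3), paste0("s", 1:9))
  splits <- monte_carlo_splits(labels, 4, 2 / 3, seed = 1)
  expect_length(splits, 4)
  for (s in splits) {
    expect_partition(s, names(labels))
    expect_length(s$train_ids, 6)
    expect_length(s$validation_ids, 3)
    # stratified: both classes on both sides
    expect_setequal(unique(labels[s$train_ids]), c("a", "b"))
    expect_setequal(unique(labels[s$validation_ids]), c("a", "b"))
  }
})

test_that("kfold splits partition validation sets with sizes differing by <= 1", {
  labels10 <- setNames(rep(c("a", "b"), 5), paste0("s", 1:10))
  splits <- kfold_splits(labels10, 5, seed = 2)
  sizes <- lengths(lapply(splits, `[[`, "validation_ids"))
  expect_equal(sizes, rep(2L, 5))
  expect_setequal(unlist(lapply(splits, `[[`, "validation_ids")), names(labels10))

  labels11 <- setNames(rep(c("a", "b"), length.out = 11), paste0("s", 1:11))
  sizes11 <- sort(lengths(lapply(kfold_splits(labels11, 5, seed = 2),
                                 `[[`, "validation_ids")), decreasing = TRUE)
  expect_equal(sizes11, c(3L, 2L, 2L, 2L, 2L))
})

test_that("splits are deterministic per seed and vary across seeds", {
  labels <- setNames(rep(c("a", "b"), 10), paste0("s", 1:20))
  expect_identical(monte_carlo_splits(labels, 3, 2 / 3, seed = 5),
                   monte_carlo_splits(labels, 3, 2 / 3, seed = 5))
  expect_false(identical(monte_carlo_splits(labels, 3, 2 / 3, seed = 5),
                         monte_carlo_splits(labels, 3, 2 / 3, seed = 6)))
  expect_identical(kfold_splits(labels, 4, seed = 5),
                   kfold_splits(labels, 4, seed = 5))
})

test_that("stratification errors on too-small classes and bad k", {
  labels <- setNames(c("a", rep("b", 9)), paste0("s", 1:10))
  expect_error(monte_carlo_splits(labels, 2, 2 / 3, seed = 1),
               class = "cb_stratification_error")
  expect_error(kfold_splits(labels, 3, seed = 1),
               class = "cb_stratification_error")
  ok <- setNames(rep(c("a", "b"), 5), paste0("s", 1:10))
  expect_error(kfold_splits(ok, 11, seed = 1), class = "cb_parameter_error")
})

test_that("partition and stratification invariants hold over random plans", {
  withr::with_seed(404, {
    for (i in 1:60) {
      n <- sample(10:40, 1)
      labels <- setNames(sample(c("a", "b"), n, replace = TRUE), paste0("s", 1:n))
      while (min(table(labels)) < 4) labels[sample(n, 1)] <- sample(c("a", "b"), 1)
      if (runif(1) < 0.5) {
        splits <- monte_carlo_splits(labels, sample(1:5, 1), runif(1, 0.4, 0.8),
                                     seed = i)
        for (s in splits) expect_partition(s, names(labels))
      } else {
        k <- sample(2:4, 1)
        splits <- kfold_splits(labels, k, seed = i)
        vals <- lapply(splits, `[[`, "validation_ids")
        expect_setequal(unlist(vals), names(labels))
        expect_equal(sum(lengths(vals)), n) # pairwise disjoint + covering
        expect_lte(diff(range(lengths(vals))), 1)
        for (s in splits) expect_partition(s, names(labels))
      }
    }
  })
})

test_that("run_basic scores every (split x classifier) cell with all metrics", {
  d <- separable_dataset(n = 30)
  plan <- benchmark_plan(outer = 2, seed = 3)
  res <- run_basic(d, c("MASS/lda", "rpart/decision_tree"), plan)
  expect_s3_class(res, "cb_result")
  expect_equal(nrow(res$metrics), 2 * 2 * 15)
  expect_equal(sort(unique(res$metrics$metric)), sort(metric_ids()))
  # perfect learner on separable data
  auc <- res$metrics[res$metrics$metric == "auroc" &
                     res$metrics$algorithm == "MASS/lda", "value"]
  expect_equal(auc, rep(1, 2))
  mmce <- res$metrics[res$metrics$metric == "mmce" &
                      res$metrics$algorithm == "MASS/lda", "value"]
  expect_equal(mmce, rep(0, 2))
  # one prediction table row per validation sample
  val_sizes <- table(res$predictions$iteration[res$predictions$algorithm == "MASS/lda"])
  expect_equal(unname(as.integer(val_sizes)), rep(10L, 2))
  # every cell has a wall-clock record
  expect_equal(nrow(res$cells), 4)
  expect_true(all(res$cells$elapsed_seconds >= 0))
})

test_that("failing cells are logged and skipped, not fatal", {
  d <- separable_dataset(n = 20)
  res <- run_basic(d, c("test/always_fails", "MASS/lda"),
                   benchmark_plan(outer = 2, seed = 9))
  expect_equal(sum(!is.na(res$cells$error)), 2)
  expect_equal(sort(unique(res$metrics$algorithm)), "MASS/lda")
})

test_that("nested selection prefers a real learner over a constant dummy", {
  d <- separable_dataset(n = 36)
  plan <- benchmark_plan(outer = 1, nested = 3, seed = 21)
  combos <- hyperparam_combos("test/lda_or_dummy")
  expect_length(combos, 2)
  sel <- select_best_combo(d, "test/lda_or_dummy", combos, plan,
                           nested_seed = 77, outer_iteration = 1)
  expect_false(isTRUE(sel$chosen$params$dummy))
  # nested records: one row per (inner x combo), exactly one combo chosen
  expect_equal(nrow(sel$records), 3 * 2)
  expect_equal(unique(sel$records$combo[sel$records$chosen]),
               sel$chosen$combo_id)
})

test_that("single-combo selection still emits nested records", {
  d <- separable_dataset(n = 30)
  plan <- benchmark_plan(outer = 1, nested = 2, seed = 13)
  sel <- select_best_combo(d, "MASS/lda", list(classifier_spec("MASS/lda")),
                           plan, nested_seed = 5)
  expect_equal(sel$chosen$combo_id, "default")
  expect_equal(nrow(sel$records), 2)
})

test_that("nested splits stay inside the outer training partition", {
  d <- separable_dataset(n = 40)
  plan <- benchmark_plan(outer = 3, nested = 3, seed = 31)
  outer <- monte_carlo_splits(setNames(d$class_labels, d$sample_ids),
                              plan$outer, plan$train_fraction, plan$seed)
  for (s in outer) {
    train <- classbench:::subset_dataset(d, sample_ids = s$train_ids)
    inner <- classbench:::make_inner_splits(
      setNames(train$class_labels, train$sample_ids), plan, seed = s$iteration)
    for (ii in inner) {
      expect_true(all(c(ii$train_ids, ii$validation_ids) %in% s$train_ids))
      expect_length(intersect(ii$validation_ids, s$validation_ids), 0)
    }
  }
})

test_that("feature-count selection clips the grid and prefers small counts on planted signal", {
  sim <- generate_signal(n_samples = 150, n_numeric = 10, n_categorical = 1,
                         informative = 2, effect_size = 3, seed = 77)
  # post-encoding feature count is 10 + 3 = 13: grid clipped to {1,3,5,10}
  plan <- benchmark_plan(outer = 1, nested = 2,
                         feature_counts = c(1, 3, 5, 10, 15, 20, 50, 200),
                         seed = 41)
  sel <- select_best_feature_count(sim$dataset,
                                   ranker_spec("univariate/anova_f"),
                                   classifier_spec("MASS/lda"), plan,
                                   nested_seed = 11)
  counts <- sort(unique(as.integer(sel$records$feature_count)))
  expect_equal(counts, c(1L, 3L, 5L, 10L))
  expect_lte(sel$chosen_count, 5)
  expect_length(sel$rankings, 2)

  single <- benchmark_plan(outer = 1, nested = 2, feature_counts = 5, seed = 41)
  sel5 <- select_best_feature_count(sim$dataset,
                                    ranker_spec("univariate/anova_f"),
                                    classifier_spec("MASS/lda"), single,
                                    nested_seed = 11)
  expect_equal(sel5$chosen_count, 5L)
})

test_that("degenerate nesting reproduces the basic run bit for bit", {
  d <- separable_dataset(n = 30)
  for (scheme in c("monte_carlo", "kfold")) {
    basic <- run_basic(d, c("MASS/lda", "rpart/decision_tree"),
                       benchmark_plan(scheme = scheme, outer = 2, seed = 55))
    nested <- run_nested(d, list(classifier_spec("MASS/lda"),
                                 classifier_spec("rpart/decision_tree")),
                         plan = benchmark_plan(scheme = scheme, outer = 2,
                                               nested = 2, seed = 55))
    expect_identical(basic$predictions, nested$predictions)
    expect_identical(basic$metrics, nested$metrics)
    d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
    write_predictions(basic, d1); write_predictions(nested, d2)
    write_metrics(basic, d1); write_metrics(nested, d2)
    expect_identical(readLines(file.path(d1, "predictions.tsv")),
                     readLines(file.path(d2, "predictions.tsv")))
    expect_identical(readLines(file.path(d1, "metrics.tsv")),
                     readLines(file.path(d2, "metrics.tsv")))
  }
})

test_that("a whole benchmark is reproducible from (dataset, plan, seed)", {
  d <- generate_null(n_samples = 40, n_numeric = 4, n_categorical = 1, seed = 6)
  plan <- benchmark_plan(outer = 2, nested = 2, seed = 14)
  a <- run_nested(d, "MASS/lda", rankers = "univariate/pearson_cor", plan = plan,
                  description = "rep")
  b <- run_nested(d, "MASS/lda", rankers = "univariate/pearson_cor", plan = plan,
                  description = "rep")
  expect_identical(a$metrics, b$metrics)
  expect_identical(a$predictions, b$predictions)
  expect_identical(a$nested, b$nested)
})

test_that("plan validation rejects bad parameters", {
  expect_error(benchmark_plan(outer = 0), class = "cb_parameter_error")
  expect_error(benchmark_plan(train_fraction = 1), class = "cb_parameter_error")
  expect_error(benchmark_plan(feature_counts = c(5, 3)), class = "cb_parameter_error")
  expect_error(benchmark_plan(selection_metric = "magic"), class = "cb_parameter_error")
})
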