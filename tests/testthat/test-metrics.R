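# The 15-metric evaluation suite.

make_predictions <- function(actual, probs_pos, levels = c("neg", "pos")) {
  probs <- cbind(1 - probs_pos, probs_pos)
  colnames(probs) <- levels
  structure(list(sample_ids = paste0("s", seq_along(actual)),
                 actual = actual,
                 predicted = levels[(probs_pos >= 0.5) + 1],
                 probabilities = probs,
                 class_levels = levels),
            class = "cb_predictions")
}

test_that("auroc matches frozen hand-computed examples", {
  # positives {0.9, 0.4}, negatives {0.5, 0.1}: 3 of 4 pairs won -> 0.75
  expect_equal(auroc(c(0.9, 0.4, 0.5, 0.1), c(TRUE, TRUE, FALSE, FALSE)), 0.75)
  expect_equal(auroc(rep(0.5, 6), rep(c(TRUE, FALSE), 3)), 0.5)
  expect_equal(auroc(c(3, 4, 1, 2), c(TRUE, TRUE, FALSE, FALSE)), 1.0)
  expect_true(is.na(auroc(c(0.2, 0.8), c(TRUE, TRUE))))
})

test_that("auroc agrees with the brute-force pairwise oracle", {
  withr::with_seed(202, {
    for (i in 1:200) {
      n <- sample(2:50, 1)
      scores <- sample(round(runif(n), 2)) # duplicates force tie handling
      truth <- runif(n) < 0.5
      if (all(truth) || !any(truth)) truth[1:2] <- c(TRUE, FALSE)
      expect_equal(auroc(scores, truth), auroc_pairwise(scores, truth),
                   tolerance = 1e-12)
    }
  })
})

test_that("auroc is invariant under strictly monotone score transforms", {
  withr::with_seed(203, {
    scores <- runif(30)
    truth <- rep(c(TRUE, FALSE), 15)
    base <- auroc(scores, truth)
    expect_equal(auroc(exp(scores), truth), base)
    expect_equal(auroc(scores^3 + 10, truth), base)
  })
})

test_that("brier score matches direct arithmetic", {
  expect_equal(brier(c(1, 0, 1), c(TRUE, FALSE, TRUE)), 0)
  expect_equal(brier(rep(0.5, 8), rep(c(TRUE, FALSE), 4)), 0.25)
  expect_equal(brier(c(0.8, 0.3), c(TRUE, FALSE)), (0.04 + 0.09) / 2)
})

test_that("confusion counts are correct and conserve n", {
  pred <- make_predictions(c("pos", "pos", "neg", "neg"), c(0.9, 0.1, 0.9, 0.1))
  counts <- confusion(pred, "pos")
  expect_equal(counts, list(tp = 1L, fp = 1L, tn = 1L, fn = 1L))
  expect_error(confusion(pred, "banana"), class = "cb_parameter_error")
  perfect <- make_predictions(c("pos", "neg"), c(0.9, 0.1))
  expect_equal(confusion(perfect, "pos")[c("fp", "fn")], list(fp = 0L, fn = 0L))
})

test_that("derived metrics match frozen formula evaluations", {
  m <- derived_metrics(list(tp = 2, tn = 3, fp = 1, fn = 1))
  expect_equal(unname(m["mcc"]), 5 / 12, tolerance = 1e-12)
  expect_equal(unname(m["f1"]), 2 / 3)
  expect_equal(unname(m["accuracy"]), 5 / 7)
  sym <- derived_metrics(list(tp = 1, fp = 1, tn = 1, fn = 1))
  expect_equal(unname(sym["mcc"]), 0)
})

test_that("0/0 denominators yield 0 with a degenerate flag", {
  m <- derived_metrics(list(tp = 0, fp = 0, tn = 4, fn = 0))
  expect_equal(unname(m["ppv"]), 0)
  expect_true(all(c("tpr", "ppv") %in% attr(m, "degenerate")))
})

test_that("algebraic identities hold on random confusion tables", {
  withr::with_seed(204, {
    for (i in 1:300) {
      counts <- as.list(sample(0:20, 4, replace = TRUE))
      names(counts) <- c("tp", "fp", "tn", "fn")
      if (sum(unlist(counts)) == 0) counts$tp <- 1
      m <- derived_metrics(counts)
      expect_equal(unname(m["accuracy"] + m["mmce"]), 1)
      expect_equal(unname(m["fdr"]), unname(1 - m["ppv"]))
      expect_equal(unname(m["balanced_accuracy"]),
                   unname((m["tpr"] + m["tnr"]) / 2))
      expect_equal(unname(m["fpr"]), unname(1 - m["tnr"]))
      expect_equal(unname(m["fnr"]), unname(1 - m["tpr"]))
      expect_equal(unname(m["recall"]), unname(m["tpr"]))
      expect_gte(unname(m["mcc"]), -1); expect_lte(unname(m["mcc"]), 1)
    }
  })
})

test_that("binary scoring emits all 15 metrics with the second level positive", {
  pred <- make_predictions(c("pos", "pos", "neg", "neg"),
                           c(0.9, 0.8, 0.2, 0.1))
  vals <- score_predictions(pred)
  expect_setequal(names(vals), metric_ids())
  expect_equal(unname(vals["auroc"]), 1)
  expect_equal(unname(vals["accuracy"]), 1)
  expect_equal(unname(vals["mmce"]), 0)
  expect_equal(unname(vals["mcc"]), 1)
  # levels sort to (neg, pos): "pos" is the lexicographically second level;
  # flipping the override flips the asymmetric metrics
  asym <- make_predictions(c("pos", "neg", "neg"), c(0.9, 0.8, 0.1))
  expect_equal(unname(score_predictions(asym)["ppv"]), 0.5)
  expect_equal(unname(score_predictions(asym, positive = "neg")["ppv"]), 1)
})

test_that("balanced binary truth gives accuracy == balanced accuracy", {
  withr::with_seed(205, {
    pred <- make_predictions(rep(c("pos", "neg"), 10), runif(20))
    vals <- score_predictions(pred)
    expect_equal(unname(vals["accuracy"]), unname(vals["balanced_accuracy"]))
  })
})

test_that("multiclass metrics are unweighted means of one-vs-rest values", {
  levels <- c("a", "b", "c")
  withr::with_seed(206, {
    n <- 30
    probs <- matrix(runif(n * 3), ncol = 3, dimnames = list(NULL, levels))
    probs <- probs / rowSums(probs)
    actual <- sample(levels, n, replace = TRUE)
    pred <- structure(list(sample_ids = paste0("s", 1:n), actual = actual,
                           predicted = levels[max.col(probs, ties.method = "first")],
                           probabilities = probs, class_levels = levels),
                      class = "cb_predictions")
    vals <- score_predictions(pred)
    per_class <- vapply(levels, function(cl) {
      counts <- confusion(pred, cl)
      unname(derived_metrics(counts)["f1"])
    }, numeric(1))
    expect_equal(unname(vals["f1"]), mean(per_class))
    per_auc <- vapply(levels, function(cl)
      auroc(probs[, cl], actual == cl), numeric(1))
    expect_equal(unname(vals["auroc"]), mean(per_auc))
  })
})

test_that("single-class truth records auroc as missing, others computed", {
  pred <- make_predictions(c("pos", "pos"), c(0.9, 0.4))
  vals <- score_predictions(pred)
  expect_true(is.na(vals["auroc"]))
  expect_false(is.na(vals["accuracy"]))
})

test_that("metrics are invariant to sample reordering", {
  withr::with_seed(207, {
    pred <- make_predictions(sample(c("pos", "neg"), 20, replace = TRUE),
                             round(runif(20), 2))
    if (length(unique(pred$actual)) < 2) pred$actual[1:2] <- c("pos", "neg")
    perm <- sample(20)
    shuffled <- pred
    shuffled$sample_ids <- pred$sample_ids[perm]
    shuffled$actual <- pred$actual[perm]
    shuffled$predicted <- pred$predicted[perm]
    shuffled$probabilities <- pred$probabilities[perm, ]
    expect_equal(score_predictions(shuffled), score_predictions(pred))
  })
})
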