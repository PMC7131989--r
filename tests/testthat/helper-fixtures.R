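# Fixtures built in code: random small datasets for property tests and
# separable datasets for learner sanity checks.

# A random mixed-type dataset with clean (exactly representable) numeric
# values so text round-trips are exact.
random_dataset <- function(n = 6, n_num = 2, n_cat = 2, missing_rate = 0,
                           labeled = TRUE, prefix = "s") {
  cols <- list()
  # keep one observed cell per column: a fully-missing column cannot carry
  # its numeric/categorical kind through delimited text
  for (j in seq_len(n_num)) {
    v <- round(stats::rnorm(n), 3)
    if (missing_rate > 0) v[-1][stats::runif(n - 1) < missing_rate] <- NA
    cols[[paste0("num", j)]] <- v
  }
  for (j in seq_len(n_cat)) {
    v <- sample(c("red", "green", "blue"), n, replace = TRUE)
    if (missing_rate > 0) v[-1][stats::runif(n - 1) < missing_rate] <- NA
    cols[[paste0("cat", j)]] <- v
  }
  values <- as.data.frame(cols, check.names = FALSE, stringsAsFactors = FALSE)
  rownames(values) <- paste0(prefix, seq_len(n))
  labels <- if (labeled) rep_len(c("yes", "no"), n) else NULL
  cb_dataset(values, class_labels = labels)
}

# Two well-separated Gaussian clouds: any reasonable learner classifies
# these perfectly.
separable_dataset <- function(n = 40, seed = 42) {
  withr::with_seed(seed, {
    half <- n / 2
    values <- data.frame(
      f1 = c(stats::rnorm(half, -4), stats::rnorm(half, 4)),
      f2 = c(stats::rnorm(half, 4), stats::rnorm(half, -4))
    )
    rownames(values) <- paste0("s", seq_len(n))
    cb_dataset(values, class_labels = rep(c("neg", "pos"), each = half))
  })
}

# Independent brute-force AUROC oracle: average over all (positive,
# negative) pairs, ties worth one half.
auroc_pairwise <- function(scores, is_positive) {
  pos <- scores[is_positive]
  neg <- scores[!is_positive]
  if (length(pos) == 0 || length(neg) == 0) return(NA_real_)
  total <- 0
  for (p in pos) for (q in neg)
    total <- total + if (p > q) 1 else if (p == q) 0.5 else 0
  total / (length(pos) * length(neg))
}

# Synthetic test-only adapters exercising the registry contract: a
# discrete-only learner, a constant coin-flip, a dummy-vs-real combo pair,
# and an always-failing learner. Registered here so every test file sees them.
register_classifier(
  "test/majority_label",
  fit = function(x, y, params) names(which.max(table(y))),
  predict = function(model, x) rep(model, nrow(x))
)
register_classifier(
  "test/coin_flip",
  fit = function(x, y, params) levels(y),
  predict = function(model, x)
    matrix(0.5, nrow = nrow(x), ncol = 2, dimnames = list(NULL, model))
)
register_classifier(
  "test/lda_or_dummy",
  fit = function(x, y, params) {
    if (isTRUE(params$dummy)) list(dummy = TRUE, levels = levels(y))
    else list(dummy = FALSE, fit = MASS::lda(x, grouping = y))
  },
  predict = function(model, x) {
    if (model$dummy)
      matrix(0.5, nrow(x), 2, dimnames = list(NULL, model$levels))
    else predict(model$fit, x)$posterior
  },
  default = list(dummy = FALSE), grid = list(dummy = c(FALSE, TRUE))
)
register_classifier(
  "test/always_fails",
  fit = function(x, y, params) stop("boom"),
  predict = function(model, x) NULL
)

expect_partition <- function(split, ids) {
  expect_length(intersect(split$train_ids, split$validation_ids), 0)
  expect_setequal(c(split$train_ids, split$validation_ids), ids)
  expect_gt(length(split$train_ids), 0)
  expect_gt(length(split$validation_ids), 0)
}
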