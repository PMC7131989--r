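# Outer and nested cross-validation.
#
# Both schemes stratify by class so small classes appear on both sides of
# every split. A benchmark is a pure function of (dataset, plan, seed): every
# cell (outer iteration x algorithm) trains under a seed derived from the
# plan seed and the cell's coordinates, and nested work draws from a disjoint
# derived stream, so a nested run with exactly one candidate option
# reproduces the basic run bit for bit.

#' Describe a benchmark: scheme, counts, search grids, seed
#'
#' @param scheme `"monte_carlo"` (repeated random splits at `train_fraction`)
#'   or `"kfold"`.
#' @param outer number of Monte Carlo iterations or folds (k).
#' @param nested number of inner iterations/folds used for hyperparameter or
#'   feature-count selection; 0 means non-nested.
#' @param train_fraction training proportion for Monte Carlo splits
#'   (default 2/3).
#' @param feature_counts ordered integer grid of top-ranked feature-subset
#'   sizes to evaluate (default 1, 3, 5, 10, 15, 20, 50, 200); clipped to the
#'   post-encoding feature count at run time.
#' @param selection_metric metric id used to pick the best option in nested
#'   folds (default `"auroc"`).
#' @param seed integer seed governing every random draw of the benchmark.
#' @return a `cb_plan` object.
#' @export
benchmark_plan <- function(scheme = c("monte_carlo", "kfold"), outer = 5,
                           nested = 0, train_fraction = 2 / 3,
                           feature_counts = c(1, 3, 5, 10, 15, 20, 50, 200),
                           selection_metric = "auroc", seed = 1L) {
  scheme <- match.arg(scheme)
  if (!is_whole(outer) || outer < 1)
    cb_stop("cb_parameter_error", "outer must be a positive integer")
  if (!is_whole(nested) || nested < 0)
    cb_stop("cb_parameter_error", "nested must be a non-negative integer")
  if (!is.numeric(train_fraction) || train_fraction <= 0 || train_fraction >= 1)
    cb_stop("cb_parameter_error", "train_fraction must be in (0, 1)")
  feature_counts <- as.integer(feature_counts)
  if (length(feature_counts) == 0 || any(feature_counts < 1) ||
      is.unsorted(feature_counts, strictly = TRUE))
    cb_stop("cb_parameter_error",
            "feature_counts must be strictly increasing integers >= 1")
  if (!selection_metric %in% metric_ids())
    cb_stop("cb_parameter_error", "unknown selection metric '%s'", selection_metric)
  structure(list(scheme = scheme, outer = as.integer(outer),
                 nested = as.integer(nested), train_fraction = train_fraction,
                 feature_counts = feature_counts,
                 selection_metric = selection_metric, seed = as.integer(seed)),
            class = "cb_plan")
}

#' @export
print.cb_plan <- function(x, ...) {
  cat(sprintf("<cb_plan> %s, outer=%d, nested=%d, train_fraction=%.3f, metric=%s, seed=%d\n",
              x$scheme, x$outer, x$nested, x$train_fraction,
              x$selection_metric, x$seed))
  invisible(x)
}

#' Stratified Monte Carlo train/validation splits
#'
#' Each iteration draws, independently and per class, a training subset of
#' about `train_fraction` of that class (at least one sample of every class
#' on each side), so class proportions are preserved to rounding.
#'
#' @param labels per-sample class labels (named by sample id, or names are
#'   generated positionally).
#' @param iterations number of splits.
#' @param train_fraction training proportion.
#' @param seed integer seed; the split list is deterministic given it.
#' @return list of `cb_split` objects (fields `iteration`, `train_ids`,
#'   `validation_ids`).
#' @export
monte_carlo_splits <- function(labels, iterations, train_fraction = 2 / 3, seed = 1L) {
  ids <- names(labels) %||% as.character(seq_along(labels))
  check_class_sizes(labels, 2L)
  with_seed(seed, lapply(seq_len(iterations), function(i) {
    train <- unlist(lapply(split(ids, labels), function(members) {
      n_tr <- min(max(round(train_fraction * length(members)), 1L),
                  length(members) - 1L)
      sample(members, n_tr)
    }), use.names = FALSE)
    new_split(i, ids[ids %in% train], setdiff(ids, train))
  }))
}

#' Stratified k-fold splits
#'
#' Validation sets partition the samples; fold sizes differ by at most one
#' and every class is spread across the folds as evenly as possible.
#'
#' @param labels per-sample class labels.
#' @param k number of folds (each class must have at least `k` members).
#' @param seed integer seed.
#' @return list of `k` `cb_split` objects.
#' @export
kfold_splits <- function(labels, k, seed = 1L) {
  ids <- names(labels) %||% as.character(seq_along(labels))
  if (!is_whole(k) || k < 2 || k > length(ids))
    cb_stop("cb_parameter_error", "k must be an integer in [2, n]")
  check_class_sizes(labels, as.integer(k))
  fold_of <- stats::setNames(integer(length(ids)), ids)
  with_seed(seed, {
    counter <- 0L
    # deal shuffled members of each class round-robin, continuing the fold
    # counter across classes: stratified and globally balanced to +/-1
    for (members in split(ids, labels)) {
      members <- sample(members)
      fold_of[members] <- (counter + seq_along(members) - 1L) %% k + 1L
      counter <- counter + length(members)
    }
  })
  lapply(seq_len(k), function(i)
    new_split(i, ids[fold_of[ids] != i], ids[fold_of[ids] == i]))
}

new_split <- function(iteration, train_ids, validation_ids) {
  structure(list(iteration = iteration, train_ids = train_ids,
                 validation_ids = validation_ids),
            class = "cb_split")
}

check_class_sizes <- function(labels, minimum) {
  sizes <- table(labels)
  if (length(sizes) < 2)
    cb_stop("cb_stratification_error", "need at least two classes to split")
  small <- names(sizes)[sizes < minimum]
  if (length(small))
    cb_stop("cb_stratification_error",
            "class(es) too small to stratify (need >= %d members): %s",
            minimum, paste(small, collapse = ", "))
  invisible(labels)
}

make_splits <- function(labels, plan, scheme_seed) {
  if (plan$scheme == "monte_carlo")
    monte_carlo_splits(labels, plan$outer, plan$train_fraction, scheme_seed)
  else
    kfold_splits(labels, plan$outer, scheme_seed)
}

make_inner_splits <- function(labels, plan, seed) {
  if (plan$scheme == "monte_carlo")
    monte_carlo_splits(labels, plan$nested, plan$train_fraction, seed)
  else
    kfold_splits(labels, plan$nested, seed)
}

labels_of <- function(d) stats::setNames(d$class_labels, d$sample_ids)

# ---------------------------------------------------------------------------
# Benchmark orchestration

empty_metric_rows <- function() {
  data.frame(description = character(0), iteration = integer(0),
             algorithm = character(0), combo = character(0),
             feature_count = character(0), metric = character(0),
             value = numeric(0), stringsAsFactors = FALSE)
}

metric_rows <- function(description, iteration, algorithm, combo,
                        feature_count, values) {
  data.frame(description = description, iteration = iteration,
             algorithm = algorithm, combo = combo,
             feature_count = as.character(feature_count),
             metric = names(values), value = unname(values),
             stringsAsFactors = FALSE)
}

prediction_rows <- function(description, iteration, algorithm, combo, pred) {
  probs <- pred$probabilities
  colnames(probs) <- paste0("prob_", pred$class_levels)
  cbind(
    data.frame(description = description, iteration = iteration,
               algorithm = algorithm, combo = combo,
               sample_id = pred$sample_ids, actual = pred$actual,
               stringsAsFactors = FALSE),
    as.data.frame(probs, row.names = NULL),
    data.frame(predicted = pred$predicted, stringsAsFactors = FALSE)
  )
}

nested_row <- function(outer, inner, algorithm, combo, feature_count,
                       metric, value, chosen = FALSE) {
  data.frame(outer_iteration = outer, inner_iteration = inner,
             algorithm = algorithm, combo = combo,
             feature_count = as.character(feature_count), metric = metric,
             value = value, chosen = chosen, stringsAsFactors = FALSE)
}

new_result <- function(description, plan, mode) {
  structure(list(description = description, plan = plan, mode = mode,
                 predictions = list(), metrics = list(), nested = list(),
                 feature_ranks = list(), cells = list(), arguments = list()),
            class = "cb_result")
}

record_cell <- function(result, iteration, algorithm, combo, elapsed,
                        error = NA_character_) {
  result$cells[[length(result$cells) + 1]] <-
    data.frame(iteration = iteration, algorithm = algorithm, combo = combo,
               elapsed_seconds = round(elapsed, 4), error = error,
               stringsAsFactors = FALSE)
  result
}

selection_value <- function(pred, metric) {
  unname(score_predictions(pred)[metric])
}

#' Run a basic (non-nested) benchmark
#'
#' For every outer split and every classifier specification: fit
#' preprocessing parameters on the training partition only, train the
#' classifier, predict the validation partition, and score all 15 metrics.
#' Per-cell wall-clock time is recorded; a failing cell is logged and skipped
#' rather than aborting the benchmark.
#'
#' @param d a labeled [cb_dataset].
#' @param classifiers list of `cb_spec` objects (or character algorithm ids,
#'   which use default hyperparameters).
#' @param plan a [benchmark_plan()] with `nested = 0`.
#' @param scale,impute,encode preprocessing flags (see [fit_preprocess()]).
#' @param description free-text label echoed into every output row.
#' @return a `cb_result` with prediction tables, tidy metric rows and a cell
#'   log.
#' @export
run_basic <- function(d, classifiers, plan = benchmark_plan(),
                      scale = TRUE, impute = TRUE, encode = TRUE,
                      description = "benchmark") {
  classifiers <- as_specs(classifiers)
  splits <- make_splits(labels_of(d), plan, plan$seed)
  result <- new_result(description, plan, "basic")

  for (split in splits) {
    parts <- preprocess_partition(d, split$train_ids, split$validation_ids,
                                  scale = scale, impute = impute, encode = encode)
    for (j in seq_along(classifiers)) {
      spec <- classifiers[[j]]
      cell_seed <- mix_seed(plan$seed, split$iteration, j)
      t0 <- proc.time()[["elapsed"]]
      outcome <- tryCatch({
        model <- train_classifier(spec, parts$train, cell_seed)
        pred <- predict_model(model, parts$validation)
        list(pred = pred, values = score_predictions(pred))
      }, error = function(e) e)
      elapsed <- proc.time()[["elapsed"]] - t0
      if (inherits(outcome, "error")) {
        result <- record_cell(result, split$iteration, spec$algorithm_id,
                              spec$combo_id, elapsed, conditionMessage(outcome))
        next
      }
      result <- record_cell(result, split$iteration, spec$algorithm_id,
                            spec$combo_id, elapsed)
      result$predictions[[length(result$predictions) + 1]] <-
        prediction_rows(description, split$iteration, spec$algorithm_id,
                        spec$combo_id, outcome$pred)
      result$metrics[[length(result$metrics) + 1]] <-
        metric_rows(description, split$iteration, spec$algorithm_id,
                    spec$combo_id, "all", outcome$values)
    }
  }
  finalize_result(result)
}

as_specs <- function(classifiers) {
  if (inherits(classifiers, "cb_spec")) classifiers <- list(classifiers)
  lapply(classifiers, function(s) {
    if (is.character(s)) classifier_spec(s) else s
  })
}

#' Select the best hyperparameter combination by nested cross-validation
#'
#' Draws nested splits from the outer training partition only, scores every
#' combination on every inner validation set with the plan's selection
#' metric, and picks the combination with the highest mean across inner
#' iterations. Ties go to the earlier combination in registry order, so the
#' default wins ties against alternatives.
#'
#' @param train the outer training partition (raw, un-preprocessed
#'   [cb_dataset]).
#' @param algorithm_id the classifier whose combinations are searched.
#' @param combos list of `cb_spec` candidates (first = default).
#' @param plan a [benchmark_plan()] with `nested >= 1`.
#' @param scale,impute,encode preprocessing flags.
#' @param nested_seed seed for the nested split stream.
#' @param outer_iteration outer iteration index (echoed into records).
#' @return list with `chosen` (a `cb_spec`) and `records` (tidy nested rows).
#' @export
select_best_combo <- function(train, algorithm_id, combos, plan,
                              scale = TRUE, impute = TRUE, encode = TRUE,
                              nested_seed = plan$seed, outer_iteration = 1L) {
  stopifnot(length(combos) >= 1, plan$nested >= 1)
  inner <- make_inner_splits(labels_of(train), plan, nested_seed)
  scores <- matrix(NA_real_, nrow = length(inner), ncol = length(combos))
  records <- list()

  for (ii in seq_along(inner)) {
    parts <- preprocess_partition(train, inner[[ii]]$train_ids,
                                  inner[[ii]]$validation_ids,
                                  scale = scale, impute = impute, encode = encode)
    for (ci in seq_along(combos)) {
      value <- tryCatch({
        model <- train_classifier(combos[[ci]], parts$train,
                                  mix_seed(nested_seed, ii, ci))
        selection_value(predict_model(model, parts$validation),
                        plan$selection_metric)
      }, error = function(e) NA_real_)
      scores[ii, ci] <- value
      records[[length(records) + 1]] <-
        nested_row(outer_iteration, ii, algorithm_id, combos[[ci]]$combo_id,
                   "all", plan$selection_metric, value)
    }
  }

  means <- colMeans(scores, na.rm = TRUE)
  means[is.nan(means)] <- -Inf
  if (all(means == -Inf))
    cb_stop("cb_selection_error",
            "all hyperparameter combinations of '%s' failed in the nested folds",
            algorithm_id)
  best <- which.max(means) # which.max takes the earliest maximum: registry order
  records <- do.call(rbind, records)
  records$chosen <- records$combo == combos[[best]]$combo_id
  list(chosen = combos[[best]], records = records)
}

#' Select the best feature-subset size by nested cross-validation
#'
#' For each inner split: the ranker orders the (post-encoding) features on
#' the inner training partition; for every count `c` in the effective grid
#' (the plan grid clipped to the available feature count, with 1 always
#' available) the classifier is trained on the top-`c` features and scored on
#' the inner validation partition. The chosen count maximizes the mean
#' selection metric across inner iterations; ties go to the smaller count
#' (parsimony).
#'
#' @param train outer training partition (raw [cb_dataset]).
#' @param ranker a `cb_ranker_spec`.
#' @param classifier a `cb_spec` used to evaluate each subset size.
#' @param plan a [benchmark_plan()] with `nested >= 1`.
#' @param scale,impute,encode preprocessing flags.
#' @param nested_seed seed for the nested split and ranking stream.
#' @param outer_iteration outer iteration index (echoed into records).
#' @return list with `chosen_count`, `rankings` (one ordered feature list per
#'   inner fold) and `records` (tidy nested rows).
#' @export
select_best_feature_count <- function(train, ranker, classifier, plan,
                                      scale = TRUE, impute = TRUE, encode = TRUE,
                                      nested_seed = plan$seed,
                                      outer_iteration = 1L) {
  stopifnot(plan$nested >= 1)
  inner <- make_inner_splits(labels_of(train), plan, nested_seed)
  rankings <- list()
  records <- list()
  grids <- list()
  score_rows <- list()

  for (ii in seq_along(inner)) {
    parts <- preprocess_partition(train, inner[[ii]]$train_ids,
                                  inner[[ii]]$validation_ids,
                                  scale = scale, impute = impute, encode = encode)
    ranking <- rank_features(ranker, parts$train, mix_seed(nested_seed, ii, 555L))
    rankings[[ii]] <- ranking
    grid <- effective_grid(plan$feature_counts, length(ranking))
    grids[[ii]] <- grid
    for (count in grid) {
      top <- ranking[seq_len(count)]
      value <- tryCatch({
        model <- train_classifier(classifier,
                                  subset_dataset(parts$train, features = top),
                                  mix_seed(nested_seed, ii, count))
        selection_value(
          predict_model(model, subset_dataset(parts$validation, features = top)),
          plan$selection_metric)
      }, error = function(e) NA_real_)
      score_rows[[length(score_rows) + 1]] <-
        data.frame(inner = ii, count = count, value = value)
      records[[length(records) + 1]] <-
        nested_row(outer_iteration, ii, classifier$algorithm_id,
                   classifier$combo_id, count, plan$selection_metric, value)
    }
  }

  scores <- do.call(rbind, score_rows)
  counts <- sort(unique(scores$count))
  means <- vapply(counts, function(cnt)
    mean(scores$value[scores$count == cnt], na.rm = TRUE), numeric(1))
  means[is.nan(means)] <- -Inf
  if (all(means == -Inf))
    cb_stop("cb_selection_error", "all feature counts failed in the nested folds")
  chosen <- counts[which.max(means)] # earliest maximum = smallest count on ties
  records <- do.call(rbind, records)
  records$chosen <- records$feature_count == as.character(chosen)
  list(chosen_count = chosen, rankings = rankings, records = records)
}

# Clip the feature-count grid to the available features. If every grid entry
# exceeds the feature count, fall back to min(grid, F) so a choice remains.
effective_grid <- function(grid, n_features) {
  eff <- grid[grid <= n_features]
  if (length(eff) == 0) eff <- min(grid[1], n_features)
  as.integer(eff)
}

#' Run a nested cross-validation benchmark
#'
#' Per outer split and classifier, nested cross-validation on the outer
#' training partition selects the best hyperparameter combination (when an
#' algorithm has more than one and `rankers` is `NULL`) or the best
#' feature-subset size per ranker (when `rankers` are given; classifiers then
#' use their supplied combination, by default the default hyperparameters,
#' matching the convention that feature-selection benchmarks are run at
#' default hyperparameters). The chosen option is retrained on the full outer
#' training partition and evaluated on the outer validation partition. No
#' outer-validation sample ever enters nested splitting, ranking, training,
#' or preprocessing-parameter estimation.
#'
#' @param d a labeled [cb_dataset].
#' @param classifiers character ids or `cb_spec` list. For hyperparameter
#'   search, character ids expand to all registered combinations via
#'   [hyperparam_combos()].
#' @param rankers optional list of `cb_ranker_spec` (or character ids); when
#'   given, runs nested feature-subset-size selection for every (ranker,
#'   classifier) pair.
#' @param plan a [benchmark_plan()] with `nested >= 1`.
#' @param scale,impute,encode preprocessing flags.
#' @param description free-text label echoed into output rows.
#' @return a `cb_result` including nested records and, for feature selection,
#'   per-inner-fold rankings with Borda aggregates.
#' @export
run_nested <- function(d, classifiers, rankers = NULL, plan = benchmark_plan(nested = 3),
                       scale = TRUE, impute = TRUE, encode = TRUE,
                       description = "benchmark") {
  if (plan$nested < 1)
    cb_stop("cb_parameter_error", "run_nested requires plan$nested >= 1")
  mode <- if (is.null(rankers)) "nested_classification" else "nested_featureselection"
  combo_sets <- if (is.null(rankers)) expand_combos(classifiers) else NULL
  classifiers <- as_specs(classifiers)
  if (!is.null(rankers)) rankers <- as_ranker_specs(rankers)
  splits <- make_splits(labels_of(d), plan, plan$seed)
  result <- new_result(description, plan, mode)

  for (split in splits) {
    parts <- preprocess_partition(d, split$train_ids, split$validation_ids,
                                  scale = scale, impute = impute, encode = encode)
    train_raw <- subset_dataset(d, sample_ids = split$train_ids)
    for (j in seq_along(classifiers)) {
      spec <- classifiers[[j]]
      cell_seed <- mix_seed(plan$seed, split$iteration, j)
      nested_seed <- mix_seed(plan$seed, split$iteration, j, 7777L)
      if (is.null(rankers)) {
        result <- run_nested_combo_cell(result, spec, combo_sets[[j]],
                                        train_raw, parts, plan, split,
                                        cell_seed, nested_seed,
                                        scale, impute, encode, description)
      } else {
        for (r in seq_along(rankers)) {
          result <- run_nested_fs_cell(result, spec, rankers[[r]], train_raw,
                                       parts, plan, split, cell_seed,
                                       mix_seed(nested_seed, r), scale, impute,
                                       encode, description)
        }
      }
    }
  }
  finalize_result(result)
}

expand_combos <- function(classifiers) {
  if (inherits(classifiers, "cb_spec")) classifiers <- list(classifiers)
  lapply(classifiers, function(s) {
    if (is.character(s)) hyperparam_combos(s) else list(s)
  })
}

as_ranker_specs <- function(rankers) {
  if (inherits(rankers, "cb_ranker_spec")) rankers <- list(rankers)
  lapply(rankers, function(s) if (is.character(s)) ranker_spec(s) else s)
}

run_nested_combo_cell <- function(result, spec, combos, train_raw, parts, plan,
                                  split, cell_seed, nested_seed,
                                  scale, impute, encode, description) {
  t0 <- proc.time()[["elapsed"]]
  outcome <- tryCatch({
    sel <- select_best_combo(train_raw, spec$algorithm_id, combos, plan,
                             scale = scale, impute = impute, encode = encode,
                             nested_seed = nested_seed,
                             outer_iteration = split$iteration)
    model <- train_classifier(sel$chosen, parts$train, cell_seed)
    pred <- predict_model(model, parts$validation)
    list(sel = sel, pred = pred, values = score_predictions(pred))
  }, error = function(e) e)
  elapsed <- proc.time()[["elapsed"]] - t0
  if (inherits(outcome, "error"))
    return(record_cell(result, split$iteration, spec$algorithm_id,
                       spec$combo_id, elapsed, conditionMessage(outcome)))
  result <- record_cell(result, split$iteration, spec$algorithm_id,
                        outcome$sel$chosen$combo_id, elapsed)
  result$nested[[length(result$nested) + 1]] <- outcome$sel$records
  result$predictions[[length(result$predictions) + 1]] <-
    prediction_rows(description, split$iteration, spec$algorithm_id,
                    outcome$sel$chosen$combo_id, outcome$pred)
  result$metrics[[length(result$metrics) + 1]] <-
    metric_rows(description, split$iteration, spec$algorithm_id,
                outcome$sel$chosen$combo_id, "all", outcome$values)
  result
}

run_nested_fs_cell <- function(result, spec, ranker, train_raw, parts, plan,
                               split, cell_seed, nested_seed,
                               scale, impute, encode, description) {
  algorithm <- paste0(spec$algorithm_id, "+", ranker$algorithm_id)
  t0 <- proc.time()[["elapsed"]]
  outcome <- tryCatch({
    sel <- select_best_feature_count(train_raw, ranker, spec, plan,
                                     scale = scale, impute = impute,
                                     encode = encode,
                                     nested_seed = nested_seed,
                                     outer_iteration = split$iteration)
    final_ranking <- rank_features(ranker, parts$train,
                                   mix_seed(cell_seed, 999L))
    top <- final_ranking[seq_len(min(sel$chosen_count, length(final_ranking)))]
    model <- train_classifier(spec, subset_dataset(parts$train, features = top),
                              cell_seed)
    pred <- predict_model(model, subset_dataset(parts$validation, features = top))
    list(sel = sel, pred = pred, values = score_predictions(pred))
  }, error = function(e) e)
  elapsed <- proc.time()[["elapsed"]] - t0
  if (inherits(outcome, "error"))
    return(record_cell(result, split$iteration, algorithm, spec$combo_id,
                       elapsed, conditionMessage(outcome)))
  sel <- outcome$sel
  records <- sel$records
  records$algorithm <- algorithm
  result <- record_cell(result, split$iteration, algorithm, spec$combo_id, elapsed)
  result$nested[[length(result$nested) + 1]] <- records
  result$feature_ranks[[length(result$feature_ranks) + 1]] <-
    list(outer_iteration = split$iteration, ranker = ranker$algorithm_id,
         rankings = sel$rankings, chosen_count = sel$chosen_count)
  result$predictions[[length(result$predictions) + 1]] <-
    prediction_rows(description, split$iteration, algorithm, spec$combo_id,
                    outcome$pred)
  result$metrics[[length(result$metrics) + 1]] <-
    metric_rows(description, split$iteration, algorithm, spec$combo_id,
                as.character(sel$chosen_count), outcome$values)
  result
}

finalize_result <- function(result) {
  result$predictions <- rbind_or_empty(result$predictions, NULL)
  result$metrics <- rbind_or_empty(result$metrics, empty_metric_rows())
  result$nested <- rbind_or_empty(result$nested, NULL)
  result$cells <- rbind_or_empty(result$cells, NULL)
  result
}

rbind_or_empty <- function(parts, empty) {
  if (length(parts) == 0) return(empty)
  do.call(rbind, c(parts, list(make.row.names = FALSE)))
}
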