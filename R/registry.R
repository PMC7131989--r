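# Algorithm registry.
#
# Classifiers and feature rankers are registered behind a uniform adapter
# contract: a classifier adapter supplies fit(x, y, params) and
# predict(model, x); a ranker adapter supplies rank(x, y, params). Adapters
# are called with a numeric feature matrix (samples x features, column names
# preserved) and a factor of class labels whose levels are the sorted
# distinct training labels. Hyperparameter grids are declarative, one YAML
# config file per algorithm shipped under inst/algorithms/.
#
# Extensibility: register_classifier()/register_ranker() are exported so
# additional algorithms can be plugged in at run time under the same
# contract.

.cb_registry <- new.env(parent = emptyenv())
.cb_registry$classifiers <- list()
.cb_registry$rankers <- list()

#' Register a classification algorithm adapter
#'
#' @param id namespaced algorithm identifier, e.g. `"rpart/decision_tree"`.
#' @param fit function `(x, y, params)` returning an opaque model handle;
#'   `x` is a numeric matrix with column names, `y` a factor whose levels are
#'   the sorted training class labels.
#' @param predict function `(model, x)` returning either a probability matrix
#'   with class-level column names or a vector of discrete labels (which is
#'   wrapped into degenerate one-hot probabilities).
#' @param default named list of default hyperparameter values.
#' @param grid named list mapping hyperparameter names to candidate value
#'   vectors; the Cartesian product defines the alternative combinations.
#' @return `id`, invisibly.
#' @export
register_classifier <- function(id, fit, predict, default = list(), grid = list()) {
  .cb_registry$classifiers[[id]] <-
    list(id = id, fit = fit, predict = predict, default = default, grid = grid)
  invisible(id)
}

#' Register a feature-ranking algorithm adapter
#'
#' @param id namespaced algorithm identifier.
#' @param rank function `(x, y, params)` returning a numeric relevance score
#'   per feature (named, higher = more relevant) or an ordered character
#'   vector of feature names (best first).
#' @param default named list of default parameter values.
#' @return `id`, invisibly.
#' @export
register_ranker <- function(id, rank, default = list()) {
  .cb_registry$rankers[[id]] <- list(id = id, rank = rank, default = default)
  invisible(id)
}

get_classifier <- function(id) {
  entry <- .cb_registry$classifiers[[id]]
  if (is.null(entry))
    cb_stop("cb_registry_error", "unknown classifier '%s' (see list_algorithms(\"classifier\"))", id)
  entry
}

get_ranker <- function(id) {
  entry <- .cb_registry$rankers[[id]]
  if (is.null(entry))
    cb_stop("cb_registry_error", "unknown ranker '%s' (see list_algorithms(\"ranker\"))", id)
  entry
}

#' List registered algorithms
#'
#' @param kind `"classifier"` or `"ranker"`.
#' @return character vector of algorithm ids in registration order (stable
#'   across calls).
#' @export
list_algorithms <- function(kind = c("classifier", "ranker")) {
  kind <- match.arg(kind)
  if (kind == "classifier") names(.cb_registry$classifiers) else names(.cb_registry$rankers)
}

#' Hyperparameter combinations of a classifier
#'
#' The first element is always the default combination (`combo_id`
#' `"default"`); alternatives follow in the deterministic order of the
#' Cartesian product over the algorithm's declared grid, skipping any
#' combination identical to the default. Each combination assigns every grid
#' parameter; parameters absent from the grid keep their default value.
#'
#' @param algorithm_id a registered classifier id.
#' @return list of `cb_spec` objects (fields `algorithm_id`, `combo_id`,
#'   `params`).
#' @export
hyperparam_combos <- function(algorithm_id) {
  entry <- get_classifier(algorithm_id)
  combos <- list(classifier_spec(algorithm_id, "default", entry$default))
  if (length(entry$grid)) {
    cells <- expand.grid(entry$grid, stringsAsFactors = FALSE,
                         KEEP.OUT.ATTRS = FALSE)
    for (i in seq_len(nrow(cells))) {
      params <- entry$default
      params[names(cells)] <- lapply(cells[i, , drop = FALSE], identity)
      if (identical(params[order(names(params))],
                    entry$default[order(names(entry$default))])) next
      combo_id <- paste(sprintf("%s=%s", names(cells),
                                vapply(cells[i, , drop = FALSE], format, character(1))),
                        collapse = ",")
      combos[[length(combos) + 1]] <- classifier_spec(algorithm_id, combo_id, params)
    }
  }
  combos
}

#' Construct classifier / ranker specifications
#'
#' @param algorithm_id a registered algorithm id.
#' @param combo_id name of the hyperparameter combination.
#' @param params named list of hyperparameter values (merged over defaults).
#' @return a `cb_spec` (classifier) or `cb_ranker_spec` (ranker) object.
#' @export
classifier_spec <- function(algorithm_id, combo_id = "default", params = NULL) {
  entry <- get_classifier(algorithm_id)
  merged <- entry$default
  if (!is.null(params)) merged[names(params)] <- params
  structure(list(algorithm_id = algorithm_id, combo_id = combo_id, params = merged),
            class = "cb_spec")
}

#' @rdname classifier_spec
#' @export
ranker_spec <- function(algorithm_id, params = NULL) {
  entry <- get_ranker(algorithm_id)
  merged <- entry$default
  if (!is.null(params)) merged[names(params)] <- params
  structure(list(algorithm_id = algorithm_id, params = merged),
            class = "cb_ranker_spec")
}

#' Train a registered classifier
#'
#' Deterministic given `(spec, train, seed)`: the adapter runs under a fixed
#' RNG state derived from `seed`. The model's class levels are the sorted
#' distinct labels of the training partition, and prediction probability
#' columns follow that order.
#'
#' @param spec a `cb_spec` from [classifier_spec()] or [hyperparam_combos()].
#' @param train a fully numeric, missing-free [cb_dataset] with class labels
#'   spanning at least two levels.
#' @param seed integer seed.
#' @return a `cb_model` handle for [predict_model()].
#' @export
train_classifier <- function(spec, train, seed = 1L) {
  stopifnot(inherits(spec, "cb_spec"))
  entry <- get_classifier(spec$algorithm_id)
  x <- dataset_matrix(train)
  if (anyNA(x))
    cb_stop("cb_apply_error", "training data contain missing values; impute first")
  if (is.null(train$class_labels))
    cb_stop("cb_apply_error", "training data carry no class labels")
  levels <- sort(unique(train$class_labels))
  if (length(levels) < 2)
    cb_stop("cb_degenerate_training_error",
            "training partition contains a single class ('%s')", levels)
  y <- factor(train$class_labels, levels = levels)
  fit <- tryCatch(
    with_seed(seed, entry$fit(x, y, spec$params)),
    error = function(e) cb_stop("cb_adapter_error", "classifier '%s' (combo '%s') failed: %s",
                                spec$algorithm_id, spec$combo_id, conditionMessage(e)))
  structure(list(algorithm_id = spec$algorithm_id, combo_id = spec$combo_id,
                 params = spec$params, fit = fit, class_levels = levels,
                 feature_names = colnames(x)),
            class = "cb_model")
}

#' Predict class probabilities with a trained model
#'
#' Output columns follow the model's class levels. Adapters that natively
#' emit only discrete labels are wrapped to emit degenerate one-hot
#' probability vectors. Every probability vector is clamped to \[0, 1\] and
#' renormalized to sum to one; the discrete prediction is the argmax, with
#' probability ties broken toward the earlier class level.
#'
#' @param model a `cb_model` from [train_classifier()].
#' @param d a [cb_dataset] whose features match the training features.
#' @return a `cb_predictions` object: fields `sample_ids`, `actual`,
#'   `predicted`, `probabilities` (matrix, one column per class level),
#'   `class_levels`.
#' @export
predict_model <- function(model, d) {
  stopifnot(inherits(model, "cb_model"))
  x <- dataset_matrix(d)
  if (!identical(colnames(x), model$feature_names))
    cb_stop("cb_apply_error", "feature set does not match the trained model")
  entry <- get_classifier(model$algorithm_id)
  raw <- tryCatch(
    entry$predict(model$fit, x),
    error = function(e) cb_stop("cb_adapter_error", "classifier '%s' prediction failed: %s",
                                model$algorithm_id, conditionMessage(e)))
  probs <- normalize_probabilities(raw, model$class_levels, nrow(x))
  rownames(probs) <- d$sample_ids
  predicted <- model$class_levels[max.col(probs, ties.method = "first")]
  structure(list(sample_ids = d$sample_ids,
                 actual = d$class_labels,
                 predicted = predicted,
                 probabilities = probs,
                 class_levels = model$class_levels),
            class = "cb_predictions")
}

normalize_probabilities <- function(raw, levels, n) {
  if (is.factor(raw) || is.character(raw)) {
    # discrete-only learner: degenerate one-hot vectors
    raw <- as.character(raw)
    probs <- matrix(0, nrow = n, ncol = length(levels),
                    dimnames = list(NULL, levels))
    probs[cbind(seq_len(n), match(raw, levels))] <- 1
    return(probs)
  }
  probs <- as.matrix(raw)
  if (is.null(colnames(probs)) && ncol(probs) == length(levels))
    colnames(probs) <- levels
  if (!all(levels %in% colnames(probs)))
    cb_stop("cb_adapter_error", "adapter probabilities lack class columns")
  probs <- probs[, levels, drop = FALSE]
  probs[!is.finite(probs)] <- 0
  probs <- pmin(pmax(probs, 0), 1)
  sums <- rowSums(probs)
  uniform <- sums <= 0
  probs[uniform, ] <- 1 / length(levels)
  sums[uniform] <- 1
  probs / sums
}

#' @export
print.cb_predictions <- function(x, ...) {
  cat(sprintf("<cb_predictions> %d samples, classes: %s\n",
              length(x$sample_ids), paste(x$class_levels, collapse = ", ")))
  invisible(x)
}

#' Rank features by estimated relevance to the class
#'
#' Returns a permutation of the training feature names, most relevant first,
#' deterministic given `(spec, train, seed)`. Score ties are broken by
#' feature name (ascending).
#'
#' @param spec a `cb_ranker_spec` from [ranker_spec()].
#' @param train a fully numeric, missing-free labeled [cb_dataset].
#' @param seed integer seed.
#' @return character vector: ordered feature names, best first.
#' @export
rank_features <- function(spec, train, seed = 1L) {
  stopifnot(inherits(spec, "cb_ranker_spec"))
  entry <- get_ranker(spec$algorithm_id)
  x <- dataset_matrix(train)
  if (anyNA(x))
    cb_stop("cb_apply_error", "training data contain missing values; impute first")
  levels <- sort(unique(train$class_labels))
  if (length(levels) < 2)
    cb_stop("cb_degenerate_training_error",
            "training partition contains a single class ('%s')", levels)
  y <- factor(train$class_labels, levels = levels)
  out <- tryCatch(
    with_seed(seed, entry$rank(x, y, spec$params)),
    error = function(e) cb_stop("cb_adapter_error", "ranker '%s' failed: %s",
                                spec$algorithm_id, conditionMessage(e)))
  if (is.character(out)) {
    if (!setequal(out, colnames(x)) || length(out) != ncol(x))
      cb_stop("cb_adapter_error", "ranker '%s' did not return a permutation of the features",
              spec$algorithm_id)
    return(out)
  }
  order_by_score(out, colnames(x))
}

# Turn a (possibly partial) named score vector into an ordered feature list:
# descending score, unscored features counted as 0, ties broken by name.
order_by_score <- function(scores, feature_names) {
  full <- stats::setNames(numeric(length(feature_names)), feature_names)
  scores <- scores[!is.na(scores)]
  keep <- intersect(names(scores), feature_names)
  full[keep] <- scores[keep]
  feature_names[order(-full, feature_names)]
}

# Load the declarative per-algorithm hyperparameter grids shipped with the
# package and attach them to the already-registered adapters.
load_algorithm_configs <- function() {
  dir <- system.file("algorithms", package = "classbench")
  if (dir == "") return(invisible())
  for (f in sort(list.files(dir, pattern = "\\.yaml$", full.names = TRUE))) {
    cfg <- yaml::read_yaml(f)
    id <- cfg$algorithm
    if (is.null(id) || is.null(.cb_registry$classifiers[[id]])) next
    if (!is.null(cfg$default))
      .cb_registry$classifiers[[id]]$default <- cfg$default
    if (!is.null(cfg$grid))
      .cb_registry$classifiers[[id]]$grid <- cfg$grid
  }
  invisible()
}
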