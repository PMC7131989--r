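#' Construct a tabular dataset of samples by features
#'
#' The canonical container used throughout classbench: a rectangular grid of
#' samples (rows) by features (columns) with per-feature type information and
#' an optional per-sample class label. Numeric cells are stored as doubles,
#' categorical cells as character strings; missing cells are `NA` regardless
#' of kind (the canonical internal missing marker; the tokens `"?"`, `"NA"`
#' and the empty string all map to it on read).
#'
#' @param values a data.frame whose rows are samples and whose columns are
#'   features. Row names are the sample identifiers. Numeric columns become
#'   numeric features, everything else categorical (character) features.
#' @param class_labels character vector of class labels, one per sample, or
#'   `NULL` for an unlabeled dataset (only useful as a merge part).
#' @param feature_kinds optional character vector (`"numeric"` or
#'   `"categorical"`), one per feature, overriding the kinds inferred from
#'   the column types of `values`.
#' @return an object of class `cb_dataset` with fields `values`,
#'   `feature_kinds`, `class_labels`, `sample_ids`, `feature_names`.
#' @examples
#' d <- cb_dataset(
#'   data.frame(f1 = c(1, 2, 3), f2 = c("a", "b", "a"),
#'              row.names = c("s1", "s2", "s3")),
#'   class_labels = c("x", "y", "x")
#' )
#' n_samples(d)
#' @export
cb_dataset <- function(values, class_labels = NULL, feature_kinds = NULL) {
  stopifnot(is.data.frame(values))
  sample_ids <- rownames(values)
  if (is.null(sample_ids)) sample_ids <- paste0("S", seq_len(nrow(values)))
  feature_names <- colnames(values)

  if (is.null(feature_kinds)) {
    feature_kinds <- vapply(values, function(col) {
      if (is.numeric(col)) "numeric" else "categorical"
    }, character(1))
  }
  feature_kinds <- unname(feature_kinds)

  # normalize storage: numeric -> double, categorical -> character
  cols <- lapply(seq_along(values), function(j) {
    col <- values[[j]]
    if (feature_kinds[j] == "numeric") as.numeric(col) else {
      col <- as.character(col)
      col[!is.na(col) & col == ""] <- NA_character_
      col
    }
  })
  names(cols) <- feature_names
  values <- as.data.frame(cols, row.names = sample_ids, check.names = FALSE,
                          stringsAsFactors = FALSE, optional = TRUE)
  colnames(values) <- feature_names

  if (!is.null(class_labels)) class_labels <- as.character(class_labels)

  d <- structure(
    list(values = values,
         feature_kinds = feature_kinds,
         class_labels = class_labels,
         sample_ids = sample_ids,
         feature_names = feature_names),
    class = "cb_dataset"
  )
  validate_dataset(d)
  d
}

validate_dataset <- function(d) {
  if (anyDuplicated(d$sample_ids))
    cb_stop("cb_integrity_error", "duplicate sample identifiers: %s",
            paste(unique(d$sample_ids[duplicated(d$sample_ids)]), collapse = ", "))
  if (anyDuplicated(d$feature_names))
    cb_stop("cb_integrity_error", "duplicate feature names: %s",
            paste(unique(d$feature_names[duplicated(d$feature_names)]), collapse = ", "))
  if (length(d$feature_kinds) != length(d$feature_names))
    cb_stop("cb_integrity_error", "feature_kinds length mismatch")
  if (!all(d$feature_kinds %in% c("numeric", "categorical")))
    cb_stop("cb_integrity_error", "feature kinds must be 'numeric' or 'categorical'")
  if (!is.null(d$class_labels)) {
    if (length(d$class_labels) != length(d$sample_ids))
      cb_stop("cb_integrity_error", "one class label per sample required")
    if (anyNA(d$class_labels))
      cb_stop("cb_integrity_error", "class labels may not be missing")
  }
  invisible(d)
}

#' @export
print.cb_dataset <- function(x, ...) {
  nlev <- if (is.null(x$class_labels)) 0L else length(unique(x$class_labels))
  cat(sprintf("<cb_dataset> %d samples x %d features (%d numeric, %d categorical)%s\n",
              n_samples(x), n_features(x),
              sum(x$feature_kinds == "numeric"),
              sum(x$feature_kinds == "categorical"),
              if (nlev) sprintf(", %d class levels", nlev) else ", unlabeled"))
  invisible(x)
}

#' Number of samples / features in a dataset
#' @param d a `cb_dataset`.
#' @return an integer count.
#' @export
n_samples <- function(d) length(d$sample_ids)

#' @rdname n_samples
#' @export
n_features <- function(d) length(d$feature_names)

#' Class levels of a dataset
#' @param d a `cb_dataset`.
#' @return sorted unique class labels, or `NULL` if unlabeled.
#' @export
class_levels <- function(d) {
  if (is.null(d$class_labels)) NULL else sort(unique(d$class_labels))
}

# Subset a dataset by sample ids and/or feature names (both by identity,
# preserving the requested order). Internal: callers pass validated ids.
subset_dataset <- function(d, sample_ids = NULL, features = NULL) {
  rows <- if (is.null(sample_ids)) seq_along(d$sample_ids) else
    match(sample_ids, d$sample_ids)
  cols <- if (is.null(features)) seq_along(d$feature_names) else
    match(features, d$feature_names)
  if (anyNA(rows)) cb_stop("cb_integrity_error", "unknown sample identifiers")
  if (anyNA(cols)) cb_stop("cb_integrity_error", "unknown feature names")
  values <- d$values[rows, cols, drop = FALSE]
  rownames(values) <- d$sample_ids[rows]
  cb_dataset(values,
             class_labels = if (is.null(d$class_labels)) NULL else d$class_labels[rows],
             feature_kinds = d$feature_kinds[cols])
}

# Numeric model matrix of a fully-numeric dataset (post-preprocessing).
dataset_matrix <- function(d) {
  if (any(d$feature_kinds != "numeric"))
    cb_stop("cb_apply_error",
            "dataset still has categorical features; one-hot encode first")
  m <- as.matrix(d$values)
  storage.mode(m) <- "double"
  rownames(m) <- d$sample_ids
  m
}
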