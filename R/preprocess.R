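# Leakage-safe preprocessing.
#
# Parameters (medians, interquartile ranges, categorical levels, imputation
# values) are fitted on a training partition only and then applied unchanged
# to any partition, so no statistic of a validation set ever leaks into the
# transformation. Application order: impute -> one-hot encode -> robust scale.

#' Fit preprocessing parameters on a training dataset
#'
#' Computes, per feature and ignoring missing cells: the observed level list
#' for categorical features (order of first appearance), the median and
#' interquartile range for numeric features (linear-interpolation quantiles,
#' R type 7), and the imputation value (median for numeric, mode for
#' categorical, ties broken by first appearance).
#'
#' @param train a [cb_dataset] to fit on.
#' @param scale,impute,encode logical flags enabling robust scaling of
#'   numeric features, imputation of missing cells, and one-hot encoding of
#'   categorical features. All default to `TRUE`.
#' @return a `cb_preprocess` parameter object for [apply_preprocess()].
#' @export
fit_preprocess <- function(train, scale = TRUE, impute = TRUE, encode = TRUE) {
  validate_dataset(train)
  if (n_samples(train) == 0)
    cb_stop("cb_fit_error", "cannot fit preprocessing on an empty training set")

  params <- lapply(seq_along(train$feature_names), function(j) {
    col <- train$values[[j]]
    obs <- col[!is.na(col)]
    if (length(obs) == 0)
      cb_stop("cb_fit_error", "feature '%s' is entirely missing in the training set",
              train$feature_names[j])
    if (train$feature_kinds[j] == "numeric") {
      q <- stats::quantile(obs, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
      list(kind = "numeric", center = q[2], iqr = q[3] - q[1], impute_value = q[2])
    } else {
      levels <- unique(obs)                 # order of first appearance
      counts <- table(factor(obs, levels = levels))
      list(kind = "categorical", levels = levels,
           impute_value = levels[which.max(counts)])
    }
  })
  names(params) <- train$feature_names
  structure(list(params = params,
                 feature_names = train$feature_names,
                 scale = scale, impute = impute, encode = encode),
            class = "cb_preprocess")
}

#' @export
print.cb_preprocess <- function(x, ...) {
  steps <- c(if (x$impute) "impute", if (x$encode) "one-hot encode", if (x$scale) "scale")
  cat(sprintf("<cb_preprocess> %d features; steps: %s\n", length(x$params),
              if (length(steps)) paste(steps, collapse = " -> ") else "none"))
  invisible(x)
}

#' Apply fitted preprocessing parameters to a dataset
#'
#' Transformations run in the order impute -> encode -> scale, each only if
#' its flag was set at fit time. Imputation replaces missing cells by the
#' fitted value. Encoding replaces a categorical feature with one binary
#' indicator per training-observed level, named `feature=level`; a level seen
#' only at apply time yields all-zero indicators. Scaling maps a numeric cell
#' x to (x - median) / IQR, with IQR 0 treated as divisor 1 so constant
#' features are centered rather than dropped.
#'
#' @param d a [cb_dataset] whose feature set equals the fitted one.
#' @param p a `cb_preprocess` from [fit_preprocess()].
#' @return a transformed [cb_dataset].
#' @export
apply_preprocess <- function(d, p) {
  stopifnot(inherits(p, "cb_preprocess"))
  if (!identical(d$feature_names, p$feature_names))
    cb_stop("cb_apply_error",
            "feature set does not match the fitted preprocessing parameters")

  out_cols <- list()
  out_kinds <- character(0)
  for (j in seq_along(d$feature_names)) {
    name <- d$feature_names[j]
    par <- p$params[[j]]
    col <- d$values[[j]]
    if (p$impute && anyNA(col)) col[is.na(col)] <- par$impute_value

    if (par$kind == "categorical" && p$encode) {
      for (lev in par$levels) {
        ind <- as.numeric(!is.na(col) & col == lev)
        out_cols[[paste0(name, "=", lev)]] <- ind
        out_kinds <- c(out_kinds, "numeric")
      }
    } else if (par$kind == "numeric" && p$scale) {
      divisor <- if (par$iqr > 0) par$iqr else 1
      out_cols[[name]] <- (as.numeric(col) - par$center) / divisor
      out_kinds <- c(out_kinds, "numeric")
    } else {
      out_cols[[name]] <- col
      out_kinds <- c(out_kinds, par$kind)
    }
  }
  values <- as.data.frame(out_cols, row.names = d$sample_ids,
                          check.names = FALSE, stringsAsFactors = FALSE,
                          optional = TRUE)
  colnames(values) <- names(out_cols)
  cb_dataset(values, class_labels = d$class_labels, feature_kinds = out_kinds)
}

# Convenience: fit on train ids, apply to train and validation partitions.
preprocess_partition <- function(d, train_ids, validation_ids,
                                 scale = TRUE, impute = TRUE, encode = TRUE) {
  train <- subset_dataset(d, sample_ids = train_ids)
  p <- fit_preprocess(train, scale = scale, impute = impute, encode = encode)
  list(train = apply_preprocess(train, p),
       validation = apply_preprocess(subset_dataset(d, sample_ids = validation_ids), p),
       params = p)
}
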