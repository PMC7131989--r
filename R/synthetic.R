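# Simulated fixture datasets.
#
# generate_null() reproduces the no-signal study condition used to verify
# that the whole pipeline behaves at chance: 500 samples, 20 standard-normal
# numeric features and 10 categorical features, with binary class labels
# drawn independently of every feature. generate_signal() plants a mean
# shift in a subset of numeric features so that recovery by rankers and the
# feature-count search can be tested against known ground truth.

#' Generate the null (no-signal) dataset
#'
#' Numeric features are standard normal, categorical features uniform over
#' their levels, and binary class labels are drawn independently of all
#' features, so any classifier's expected AUROC is 0.5.
#'
#' @param n_samples number of samples (default 500).
#' @param n_numeric standard-normal numeric features (default 20).
#' @param n_categorical categorical features (default 10).
#' @param n_levels levels per categorical feature (default 3).
#' @param class_balance probability of the second class (default 0.5).
#' @param seed integer seed; the dataset is deterministic given it.
#' @return a labeled [cb_dataset] with classes `"ClassA"`/`"ClassB"`.
#' @export
generate_null <- function(n_samples = 500, n_numeric = 20, n_categorical = 10,
                          n_levels = 3, class_balance = 0.5, seed = 1L) {
  stopifnot(n_samples >= 4, n_numeric >= 0, n_categorical >= 0, n_levels >= 2,
            class_balance > 0, class_balance < 1)
  with_seed(seed, {
    cols <- list()
    for (j in seq_len(n_numeric))
      cols[[sprintf("num%02d", j)]] <- stats::rnorm(n_samples)
    for (j in seq_len(n_categorical))
      cols[[sprintf("cat%02d", j)]] <-
        sample(paste0("level", seq_len(n_levels)), n_samples, replace = TRUE)
    labels <- ifelse(stats::runif(n_samples) < class_balance, "ClassB", "ClassA")
    # guarantee both classes appear even at small n
    if (length(unique(labels)) < 2) labels[1] <- setdiff(c("ClassA", "ClassB"), labels)[1]
    values <- as.data.frame(cols, check.names = FALSE, stringsAsFactors = FALSE)
    rownames(values) <- sprintf("S%04d", seq_len(n_samples))
    cb_dataset(values, class_labels = labels)
  })
}

#' Generate a planted-signal dataset
#'
#' Identical to [generate_null()] except that the first `informative`
#' numeric features have class-conditional means 0 (first class) and
#' `effect_size` (second class), in units of the feature standard deviation.
#' The informative feature names are returned alongside the dataset so
#' recovery tests need no hidden state.
#'
#' @param n_samples,n_numeric,n_categorical,n_levels,class_balance,seed as in
#'   [generate_null()].
#' @param informative number of signal-bearing numeric features (default 3).
#' @param effect_size between-class mean shift in standard-deviation units
#'   (default 2; 0 recovers the null distribution).
#' @return list with `dataset` (a [cb_dataset]) and `informative` (character
#'   vector of planted feature names).
#' @export
generate_signal <- function(n_samples = 500, n_numeric = 20, n_categorical = 10,
                            n_levels = 3, class_balance = 0.5,
                            informative = 3, effect_size = 2, seed = 1L) {
  if (informative > n_numeric)
    cb_stop("cb_parameter_error",
            "informative (%d) exceeds the number of numeric features (%d)",
            informative, n_numeric)
  d <- generate_null(n_samples = n_samples, n_numeric = n_numeric,
                     n_categorical = n_categorical, n_levels = n_levels,
                     class_balance = class_balance, seed = seed)
  planted <- d$feature_names[seq_len(informative)]
  shift <- as.numeric(d$class_labels == "ClassB") * effect_size
  for (f in planted) d$values[[f]] <- d$values[[f]] + shift
  list(dataset = d, informative = planted)
}
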