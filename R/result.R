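# S3 methods for benchmark results.

#' @export
print.cb_result <- function(x, ...) {
  n_algo <- length(unique(x$metrics$algorithm))
  n_iter <- length(unique(x$metrics$iteration))
  cat(sprintf("<cb_result> mode=%s, %d algorithm(s) x %d iteration(s), %d metric rows\n",
              x$mode, n_algo, n_iter, nrow(x$metrics)))
  n_err <- if (is.null(x$cells)) 0L else sum(!is.na(x$cells$error))
  if (n_err) cat(sprintf("  %d cell(s) failed (see the run log)\n", n_err))
  invisible(x)
}

#' Summarize a benchmark result
#'
#' Medians of a metric across cross-validation iterations, one row per
#' algorithm.
#'
#' @param object a `cb_result`.
#' @param metric metric id to summarize (default `"auroc"`).
#' @param ... unused.
#' @return a data.frame with columns `algorithm`, `metric`, `median`,
#'   `iterations`.
#' @export
summary.cb_result <- function(object, metric = "auroc", ...) {
  if (!metric %in% metric_ids())
    cb_stop("cb_parameter_error", "unknown metric '%s'", metric)
  rows <- object$metrics[object$metrics$metric == metric, , drop = FALSE]
  if (nrow(rows) == 0)
    return(data.frame(algorithm = character(0), metric = character(0),
                      median = numeric(0), iterations = integer(0),
                      stringsAsFactors = FALSE))
  split_rows <- split(rows, rows$algorithm)
  out <- data.frame(
    algorithm = names(split_rows),
    metric = metric,
    median = vapply(split_rows, function(r) stats::median(r$value, na.rm = TRUE),
                    numeric(1)),
    iterations = vapply(split_rows, nrow, integer(1)),
    stringsAsFactors = FALSE, row.names = NULL
  )
  out[order(out$algorithm), , drop = FALSE]
}
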