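# Borda-count rank aggregation and tidy tab-delimited writers.
#
# Five outputs per run: predictions, metrics, nested records, feature ranks,
# and a log. All files are rectangular, header-first, tab-delimited, encode
# missing values as "NA", and are byte-reproducible under a fixed seed.

#' Aggregate ranked feature lists by Borda count
#'
#' A feature at 1-based position `r` in one list of length `F` receives
#' `F - r` points (a last-place feature scores 0); points are summed across
#' lists and features are ordered by descending total, ties broken by feature
#' name ascending. With full permutations this ordering is identical to
#' ordering by ascending mean rank.
#'
#' @param rankings list of character vectors, each a permutation of the same
#'   feature set (best first).
#' @return a data.frame with columns `feature`, `points`, `mean_rank`,
#'   `rank`, ordered best first.
#' @export
borda_aggregate <- function(rankings) {
  stopifnot(is.list(rankings), length(rankings) >= 1)
  features <- sort(rankings[[1]])
  n_feat <- length(features)
  for (r in rankings) {
    if (length(r) != n_feat || !identical(sort(r), features))
      cb_stop("cb_aggregation_error",
              "all rankings must be permutations of the same feature set")
  }
  points <- stats::setNames(numeric(n_feat), features)
  rank_sum <- stats::setNames(numeric(n_feat), features)
  for (r in rankings) {
    pos <- seq_len(n_feat)
    points[r] <- points[r] + (n_feat - pos)
    rank_sum[r] <- rank_sum[r] + pos
  }
  ord <- order(-points, features)
  data.frame(feature = features[ord],
             points = unname(points[ord]),
             mean_rank = unname(rank_sum[ord]) / length(rankings),
             rank = seq_len(n_feat),
             stringsAsFactors = FALSE)
}

write_tsv <- function(df, path) {
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  ok <- tryCatch({
    utils::write.table(df, path, sep = "\t", quote = FALSE, na = "NA",
                       row.names = FALSE, col.names = TRUE)
    TRUE
  }, error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok) cb_stop("cb_io_error", "cannot write %s", path)
  invisible(path)
}

#' Write the tidy output files of a benchmark
#'
#' @param result a `cb_result` from [run_basic()] or [run_nested()].
#' @param dir output directory (created if needed).
#' @return the written file path, invisibly.
#' @name writers
NULL

#' @rdname writers
#' @export
write_predictions <- function(result, dir) {
  df <- result$predictions
  if (is.null(df)) {
    df <- data.frame(description = character(0), iteration = integer(0),
                     algorithm = character(0), combo = character(0),
                     sample_id = character(0), actual = character(0),
                     predicted = character(0), stringsAsFactors = FALSE)
  } else {
    df <- df[order(df$iteration, df$algorithm, df$sample_id), , drop = FALSE]
  }
  write_tsv(df, file.path(dir, "predictions.tsv"))
}

#' @rdname writers
#' @export
write_metrics <- function(result, dir) {
  df <- result$metrics
  df <- df[order(df$iteration, df$algorithm, df$combo, df$metric), , drop = FALSE]
  write_tsv(df, file.path(dir, "metrics.tsv"))
}

#' @rdname writers
#' @export
write_nested <- function(result, dir) {
  df <- result$nested
  if (is.null(df))
    df <- data.frame(outer_iteration = integer(0), inner_iteration = integer(0),
                     algorithm = character(0), combo = character(0),
                     feature_count = character(0), metric = character(0),
                     value = numeric(0), chosen = logical(0),
                     stringsAsFactors = FALSE)
  df <- df[order(df$outer_iteration, df$algorithm, df$inner_iteration,
                 df$combo, df$feature_count), , drop = FALSE]
  write_tsv(df, file.path(dir, "nested.tsv"))
}

#' @rdname writers
#' @export
write_feature_ranks <- function(result, dir) {
  rows <- lapply(result$feature_ranks, function(fr) {
    agg <- borda_aggregate(fr$rankings)
    data.frame(outer_iteration = fr$outer_iteration, ranker = fr$ranker,
               feature = agg$feature, borda_points = agg$points,
               mean_rank = agg$mean_rank, final_rank = agg$rank,
               stringsAsFactors = FALSE)
  })
  df <- if (length(rows)) do.call(rbind, rows) else
    data.frame(outer_iteration = integer(0), ranker = character(0),
               feature = character(0), borda_points = numeric(0),
               mean_rank = numeric(0), final_rank = integer(0),
               stringsAsFactors = FALSE)
  df <- df[order(df$outer_iteration, df$ranker, df$final_rank), , drop = FALSE]
  write_tsv(df, file.path(dir, "feature_ranks.tsv"))
}

#' @rdname writers
#' @export
write_log <- function(result, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  path <- file.path(dir, "log.txt")
  plan <- result$plan
  lines <- c(
    sprintf("classbench version: %s",
            as.character(utils::packageVersion("classbench"))),
    sprintf("description: %s", result$description),
    sprintf("mode: %s", result$mode),
    sprintf("scheme: %s", plan$scheme),
    sprintf("outer: %d", plan$outer),
    sprintf("nested: %d", plan$nested),
    sprintf("train_fraction: %s", format(plan$train_fraction, digits = 10)),
    sprintf("feature_counts: %s", paste(plan$feature_counts, collapse = ",")),
    sprintf("selection_metric: %s", plan$selection_metric),
    sprintf("seed: %d", plan$seed)
  )
  if (length(result$arguments))
    lines <- c(lines, vapply(seq_along(result$arguments), function(i)
      sprintf("argument %s: %s", names(result$arguments)[i],
              paste(result$arguments[[i]], collapse = ",")), character(1)))
  lines <- c(lines, "", "cell timings (seconds):")
  cells <- result$cells
  if (!is.null(cells) && nrow(cells)) {
    lines <- c(lines, vapply(seq_len(nrow(cells)), function(i) {
      base <- sprintf("iteration=%d algorithm=%s combo=%s elapsed=%s",
                      cells$iteration[i], cells$algorithm[i], cells$combo[i],
                      format(cells$elapsed_seconds[i], digits = 6))
      if (!is.na(cells$error[i]))
        base <- paste0(base, " ERROR: ", cells$error[i])
      base
    }, character(1)))
  }
  ok <- tryCatch({ writeLines(lines, path); TRUE }, error = function(e) FALSE)
  if (!ok) cb_stop("cb_io_error", "cannot write %s", path)
  invisible(path)
}

#' Write all five outputs of a run
#'
#' @param result a `cb_result`.
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_outputs <- function(result, dir) {
  write_predictions(result, dir)
  write_metrics(result, dir)
  write_nested(result, dir)
  write_feature_ranks(result, dir)
  write_log(result, dir)
  invisible(dir)
}
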