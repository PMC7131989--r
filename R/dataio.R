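# Reading and writing the supported tabular dialects.
#
# Supported extensions: .tsv .csv (samples as rows), .ttsv .tcsv (transposed:
# features as rows, samples as columns), .arff, each optionally wrapped in
# .gz. Delimited files carry a header row and a leading sample-identifier
# column; the class column is named "Class" (case-insensitive) by default.
# ARFF files use their last attribute as the class by convention; a leading
# string attribute named sample_id/id (case-insensitive) carries identifiers.

SUPPORTED_EXTENSIONS <- c("tsv", "csv", "ttsv", "tcsv", "arff")
MISSING_TOKENS <- c("?", "NA", "")

parse_path <- function(path) {
  ext <- tolower(tools::file_ext(path))
  gz <- identical(ext, "gz")
  if (gz) ext <- tolower(tools::file_ext(sub("\\.gz$", "", path, ignore.case = TRUE)))
  if (!ext %in% SUPPORTED_EXTENSIONS)
    cb_stop("cb_format_error",
            "unsupported file extension '%s' (expected one of %s, optionally .gz)",
            ext, paste(SUPPORTED_EXTENSIONS, collapse = "/"))
  list(ext = ext, gz = gz)
}

# Materialize a (possibly gzipped) text file as a plain temporary file.
# ARFF parsing needs a seekable file and all supported formats are
# line-oriented, so decompressing through a line copy is safe.
as_plain_file <- function(path, gz) {
  if (!gz) return(path)
  tmp <- tempfile(fileext = paste0(".", tools::file_ext(sub("\\.gz$", "", path))))
  con <- gzfile(path, "r")
  on.exit(close(con))
  writeLines(readLines(con), tmp)
  tmp
}

#' Read a tabular dataset
#'
#' Parses any supported dialect into a [cb_dataset]. Transposed dialects
#' (`.ttsv`/`.tcsv`) are re-oriented so samples are rows; `.gz` files are
#' decompressed transparently. The tokens `"?"`, `"NA"` and the empty string
#' are read as missing. Feature kinds are inferred per column (a column whose
#' non-missing cells all parse as numbers is numeric; anything else is
#' categorical); ARFF attribute declarations override inference.
#'
#' @param path path to the file.
#' @param class_column name of the class column in delimited files
#'   (case-insensitive match; default `"Class"`). Ignored for ARFF, where the
#'   last attribute is the class unless an attribute matches this name.
#' @param require_class if `TRUE` (default), a missing class column is a
#'   schema error; set `FALSE` to read an unlabeled file for merging.
#' @return a [cb_dataset].
#' @seealso [write_dataset()], [merge_datasets()]
#' @export
read_dataset <- function(path, class_column = "Class", require_class = TRUE) {
  if (!file.exists(path))
    cb_stop("cb_io_error", "file not found: %s", path)
  info <- parse_path(path)
  plain <- as_plain_file(path, info$gz)
  if (info$ext == "arff") {
    read_arff_dataset(plain, class_column, require_class)
  } else {
    sep <- if (info$ext %in% c("tsv", "ttsv")) "\t" else ","
    transposed <- info$ext %in% c("ttsv", "tcsv")
    read_delim_dataset(plain, sep, transposed, class_column, require_class)
  }
}

read_delim_dataset <- function(path, sep, transposed, class_column, require_class) {
  df <- tryCatch(
    utils::read.table(path, sep = sep, header = TRUE, check.names = FALSE,
                      colClasses = "character", quote = "\"",
                      comment.char = "", na.strings = MISSING_TOKENS,
                      stringsAsFactors = FALSE),
    error = function(e) cb_stop("cb_parse_error", "cannot parse %s: %s",
                                path, conditionMessage(e)))
  if (ncol(df) < 2)
    cb_stop("cb_parse_error", "%s: need an identifier column plus data columns", path)
  ids <- as.character(df[[1]])
  grid <- as.matrix(df[-1])
  rownames(grid) <- ids
  if (transposed) grid <- t(grid)
  finish_dataset(grid, class_column, require_class)
}

read_arff_dataset <- function(path, class_column, require_class) {
  df <- tryCatch(foreign::read.arff(path),
                 error = function(e) cb_stop("cb_parse_error", "cannot parse %s: %s",
                                             path, conditionMessage(e)))
  nm <- colnames(df)
  id_col <- which(tolower(nm) %in% c("sample_id", "id"))[1]
  if (!is.na(id_col)) {
    ids <- as.character(df[[id_col]])
    df <- df[, -id_col, drop = FALSE]
    nm <- colnames(df)
  } else {
    ids <- paste0("S", seq_len(nrow(df)))
  }
  class_col <- which(tolower(nm) == tolower(class_column))[1]
  if (is.na(class_col)) class_col <- ncol(df) # arff convention: last attribute
  if (is.na(class_col) || ncol(df) == 0) {
    if (require_class) cb_stop("cb_schema_error", "%s: no class attribute", path)
    labels <- NULL
  } else {
    labels <- as.character(df[[class_col]])
    if (anyNA(labels))
      cb_stop("cb_integrity_error", "%s: missing class labels", path)
    df <- df[, -class_col, drop = FALSE]
  }
  kinds <- vapply(df, function(col) if (is.numeric(col)) "numeric" else "categorical",
                  character(1))
  values <- df
  rownames(values) <- NULL
  for (j in seq_along(values)) if (!is.numeric(values[[j]]))
    values[[j]] <- as.character(values[[j]])
  rownames(values) <- make_ids_unique(ids)
  cb_dataset(values, class_labels = labels, feature_kinds = unname(kinds))
}

make_ids_unique <- function(ids) {
  if (anyDuplicated(ids))
    cb_stop("cb_integrity_error", "duplicate sample identifiers: %s",
            paste(unique(ids[duplicated(ids)]), collapse = ", "))
  ids
}

# Shared tail of delimited parsing: `grid` is a character matrix with samples
# as rows (already re-oriented), sample ids as row names, feature/class names
# as column names.
finish_dataset <- function(grid, class_column, require_class) {
  ids <- make_ids_unique(rownames(grid))
  nm <- colnames(grid)
  if (anyDuplicated(nm))
    cb_stop("cb_integrity_error", "duplicate feature names: %s",
            paste(unique(nm[duplicated(nm)]), collapse = ", "))
  class_col <- which(tolower(nm) == tolower(class_column))[1]
  labels <- NULL
  if (!is.na(class_col)) {
    labels <- grid[, class_col]
    if (anyNA(labels))
      cb_stop("cb_integrity_error", "missing class labels")
    grid <- grid[, -class_col, drop = FALSE]
    nm <- colnames(grid)
  } else if (require_class) {
    cb_stop("cb_schema_error", "no class column named '%s' found", class_column)
  }
  kinds <- apply(grid, 2, infer_kind)
  cols <- lapply(seq_len(ncol(grid)), function(j) {
    if (kinds[j] == "numeric") as.numeric(grid[, j]) else grid[, j]
  })
  names(cols) <- nm
  values <- as.data.frame(cols, row.names = ids, check.names = FALSE,
                          stringsAsFactors = FALSE, optional = TRUE)
  colnames(values) <- nm
  cb_dataset(values, class_labels = unname(labels), feature_kinds = unname(kinds))
}

infer_kind <- function(col) {
  obs <- col[!is.na(col)]
  if (length(obs) && !anyNA(suppressWarnings(as.numeric(obs)))) "numeric" else "categorical"
}

#' Write a dataset to any supported dialect
#'
#' The inverse of [read_dataset()]: the written file reads back to a dataset
#' equal to `d` up to numeric-text formatting. Missing cells are written as
#' `NA` in delimited files and as `?` in ARFF. A `.gz` suffix gzip-compresses
#' the output.
#'
#' @param d a [cb_dataset].
#' @param path output path; the extension selects the dialect.
#' @param class_column name used for the class column (default `"Class"`).
#' @return `path`, invisibly.
#' @export
write_dataset <- function(d, path, class_column = "Class") {
  info <- parse_path(path)
  target <- if (info$gz) tempfile(fileext = paste0(".", info$ext)) else path
  if (info$ext == "arff") {
    write_arff_dataset(d, target, class_column)
  } else {
    sep <- if (info$ext %in% c("tsv", "ttsv")) "\t" else ","
    transposed <- info$ext %in% c("ttsv", "tcsv")
    write_delim_dataset(d, target, sep, transposed, class_column)
  }
  if (info$gz) {
    con <- tryCatch(gzfile(path, "wb"),
                    error = function(e) cb_stop("cb_io_error", "cannot write %s", path))
    on.exit(close(con))
    writeLines(readLines(target), con)
  }
  invisible(path)
}

format_cells <- function(d) {
  out <- vapply(seq_along(d$feature_names), function(j) {
    col <- d$values[[j]]
    if (d$feature_kinds[j] == "numeric") {
      s <- vapply(col, function(x) if (is.na(x)) NA_character_ else
        format(x, digits = 15, scientific = FALSE, trim = TRUE), character(1))
    } else {
      s <- as.character(col)
    }
    s
  }, character(n_samples(d)))
  out <- matrix(out, nrow = n_samples(d),
                dimnames = list(d$sample_ids, d$feature_names))
  out
}

write_delim_dataset <- function(d, path, sep, transposed, class_column) {
  grid <- format_cells(d)
  if (!is.null(d$class_labels)) grid <- cbind(grid, d$class_labels)
  colnames(grid) <- c(d$feature_names,
                      if (!is.null(d$class_labels)) class_column)
  corner <- if (transposed) "feature" else "sample_id"
  if (transposed) grid <- t(grid)
  lines <- c(
    paste(c(corner, colnames(grid)), collapse = sep),
    vapply(seq_len(nrow(grid)), function(i) {
      cells <- grid[i, ]
      cells[is.na(cells)] <- "NA"
      paste(c(rownames(grid)[i], cells), collapse = sep)
    }, character(1))
  )
  ok <- tryCatch({ writeLines(lines, path); TRUE },
                 error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok) cb_stop("cb_io_error", "cannot write %s", path)
  invisible(path)
}

write_arff_dataset <- function(d, path, class_column) {
  df <- data.frame(sample_id = d$sample_ids, stringsAsFactors = FALSE)
  for (j in seq_along(d$feature_names)) {
    col <- d$values[[j]]
    df[[d$feature_names[j]]] <-
      if (d$feature_kinds[j] == "numeric") col else factor(col)
  }
  if (!is.null(d$class_labels)) df[[class_column]] <- factor(d$class_labels)
  ok <- tryCatch({ foreign::write.arff(df, path); TRUE },
                 error = function(e) FALSE)
  if (!ok) cb_stop("cb_io_error", "cannot write %s", path)
  invisible(path)
}

#' Merge datasets on overlapping sample identifiers
#'
#' Restricts every part to the samples present in all parts (keeping the
#' first part's order) and concatenates their feature columns. At most one
#' part may carry class labels, or all labeled parts must agree on the shared
#' samples.
#'
#' @param parts a list of [cb_dataset] objects (length >= 1).
#' @return a [cb_dataset] over the intersected samples and concatenated
#'   features.
#' @export
merge_datasets <- function(parts) {
  stopifnot(is.list(parts), length(parts) >= 1)
  lapply(parts, validate_dataset)
  if (length(parts) == 1) return(parts[[1]])

  shared <- Reduce(intersect, lapply(parts, function(p) p$sample_ids))
  shared <- parts[[1]]$sample_ids[parts[[1]]$sample_ids %in% shared]
  if (length(shared) == 0)
    cb_stop("cb_merge_error", "no sample identifiers shared by all parts")

  all_features <- unlist(lapply(parts, function(p) p$feature_names))
  if (anyDuplicated(all_features))
    cb_stop("cb_integrity_error", "feature-name collision across parts: %s",
            paste(unique(all_features[duplicated(all_features)]), collapse = ", "))

  labeled <- Filter(function(p) !is.null(p$class_labels), parts)
  labels <- NULL
  if (length(labeled)) {
    ref <- labeled[[1]]
    labels <- ref$class_labels[match(shared, ref$sample_ids)]
    for (p in labeled[-1]) {
      other <- p$class_labels[match(shared, p$sample_ids)]
      if (!identical(labels, other))
        cb_stop("cb_integrity_error",
                "class-label disagreement on shared samples")
    }
  }

  values <- do.call(cbind, lapply(parts, function(p) {
    v <- p$values[match(shared, p$sample_ids), , drop = FALSE]
    rownames(v) <- shared
    v
  }))
  cb_dataset(values, class_labels = labels,
             feature_kinds = unlist(lapply(parts, function(p) p$feature_kinds)))
}
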