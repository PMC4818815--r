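#' @useDynLib shapleyFS, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats cor sd var quantile rnorm predict
#' @importFrom utils combn head write.table
NULL

fs_error <- function(class, msg, ...) {
  stop(errorCondition(sprintf(msg, ...),
                      class = c(class, "shapleyFS_error", "error")))
}

#' Construct a validated expression dataset
#'
#' The container every other function in the package consumes: a numeric
#' samples-by-features matrix, one class label per sample, and unique
#' feature/sample identifiers.
#'
#' Invariants enforced: all entries finite (no NA/NaN/Inf), at least two
#' classes with at least two samples each, unique feature and sample ids.
#' Violations raise classed conditions (`shapleyFS_nonfinite`,
#' `shapleyFS_too_few_classes`, `shapleyFS_duplicate_ids`, ...), so callers
#' can distinguish failure modes programmatically.
#'
#' @param matrix numeric matrix, samples in rows, features in columns.
#' @param labels vector of class labels, one per row of `matrix`; coerced to
#'   factor.
#' @param feature_ids,sample_ids optional character vectors of unique ids;
#'   defaults are taken from `dimnames(matrix)` or generated.
#' @return An object of class `ExpressionDataset`: a list with elements
#'   `matrix`, `labels` (factor), `feature_ids`, `sample_ids`.
#' @examples
#' m <- matrix(rnorm(20), nrow = 4)
#' expression_dataset(m, labels = c("a", "a", "b", "b"))
#' @export
expression_dataset <- function(matrix, labels, feature_ids = NULL,
                               sample_ids = NULL) {
  if (!is.matrix(matrix) || !is.numeric(matrix))
    fs_error("shapleyFS_bad_matrix", "expression data must be a numeric matrix")
  n_s <- nrow(matrix); n_f <- ncol(matrix)
  if (length(labels) != n_s)
    fs_error("shapleyFS_bad_labels",
             "got %d labels for %d samples", length(labels), n_s)
  if (!all(is.finite(matrix)))
    fs_error("shapleyFS_nonfinite",
             "expression matrix contains missing or non-finite values")
  labels <- factor(labels)
  if (nlevels(labels) < 2L)
    fs_error("shapleyFS_too_few_classes",
             "need >= 2 distinct classes, got %d", nlevels(labels))
  if (any(table(labels) < 2L))
    fs_error("shapleyFS_too_few_classes",
             "every class needs >= 2 samples")
  if (is.null(feature_ids))
    feature_ids <- colnames(matrix) %||% sprintf("F%04d", seq_len(n_f))
  if (is.null(sample_ids))
    sample_ids <- rownames(matrix) %||% sprintf("S%04d", seq_len(n_s))
  feature_ids <- as.character(feature_ids)
  sample_ids <- as.character(sample_ids)
  if (length(feature_ids) != n_f || anyDuplicated(feature_ids))
    fs_error("shapleyFS_duplicate_ids", "feature_ids must be unique, length %d", n_f)
  if (length(sample_ids) != n_s || anyDuplicated(sample_ids))
    fs_error("shapleyFS_duplicate_ids", "sample_ids must be unique, length %d", n_s)
  dimnames(matrix) <- list(sample_ids, feature_ids)
  structure(list(matrix = matrix, labels = labels,
                 feature_ids = feature_ids, sample_ids = sample_ids),
            class = "ExpressionDataset")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.ExpressionDataset <- function(x, ...) {
  cat(sprintf("ExpressionDataset: %d samples x %d features, %d classes (%s)\n",
              nrow(x$matrix), ncol(x$matrix), nlevels(x$labels),
              paste(sprintf("%s:%d", levels(x$labels), tabulate(x$labels)),
                    collapse = ", ")))
  invisible(x)
}

#' @export
dim.ExpressionDataset <- function(x) dim(x$matrix)

infer_sep <- function(path) {
  if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
}

#' Load an expression dataset from delimited text
#'
#' Reads a CSV/TSV with a header row. The default orientation is samples in
#' rows and features in columns, with the class label in the column named by
#' `label_column`. Many microarray dumps ship genes-in-rows; pass
#' `transpose = TRUE` for a features-by-samples file whose first column holds
#' feature ids and which contains a row with id `label_column` carrying the
#' class labels.
#'
#' Missing or non-numeric expression cells are a hard error; no imputation is
#' performed.
#'
#' @param path path to a delimited text file with a header row.
#' @param label_column name of the label column (or, with transpose, the label
#'   row's id). Default `"class"`.
#' @param transpose logical; file is features x samples and must be flipped.
#' @param sep field separator; inferred from the extension when `NULL`
#'   (`.csv` is comma, anything else tab).
#' @return An [expression_dataset()].
#' @export
load_dataset <- function(path, label_column = "class", transpose = FALSE,
                         sep = NULL) {
  if (!file.exists(path))
    fs_error("shapleyFS_missing_file", "no such file: %s", path)
  sep <- sep %||% infer_sep(path)
  dt <- data.table::fread(path, sep = sep, header = TRUE,
                          data.table = FALSE, colClasses = "character")
  if (transpose) {
    row_ids <- dt[[1L]]
    sample_ids <- colnames(dt)[-1L]
    lab_row <- which(row_ids == label_column)
    if (length(lab_row) != 1L)
      fs_error("shapleyFS_missing_label",
               "label row '%s' not found (or duplicated)", label_column)
    labels <- as.character(dt[lab_row, -1L])
    feat <- dt[-lab_row, , drop = FALSE]
    feature_ids <- feat[[1L]]
    mat_chr <- t(as.matrix(feat[, -1L, drop = FALSE]))
  } else {
    if (!label_column %in% colnames(dt))
      fs_error("shapleyFS_missing_label",
               "label column '%s' not found", label_column)
    labels <- dt[[label_column]]
    keep <- setdiff(colnames(dt), label_column)
    # a leading non-numeric id column (common in exports) becomes sample ids
    sample_ids <- NULL
    if (length(keep) > 1L &&
        all(is.na(suppressWarnings(as.numeric(dt[[keep[1L]]]))))) {
      sample_ids <- dt[[keep[1L]]]
      keep <- keep[-1L]
    }
    feature_ids <- keep
    mat_chr <- as.matrix(dt[, keep, drop = FALSE])
  }
  mat <- suppressWarnings(array(as.numeric(mat_chr), dim = dim(mat_chr)))
  if (anyNA(mat)) {
    bad <- which(is.na(mat), arr.ind = TRUE)[1L, ]
    fs_error("shapleyFS_non_numeric",
             "non-numeric or missing expression value at row %d, column %d",
             bad[1L], bad[2L])
  }
  expression_dataset(mat, labels, feature_ids = feature_ids,
                     sample_ids = sample_ids)
}

#' Write a selection result as a ranked TSV
#'
#' Columns: rank, feature_id, victory_score, shapley_weight, su_relevance.
#' Scores are written with 17 significant digits so a re-read reproduces the
#' ranking bit-for-bit.
#'
#' @param result a `SelectionResult` from [forward_select()].
#' @param weights the `ShapleyWeights` used for the selection.
#' @param path output file path.
#' @param feature_ids character ids for the feature indices in `result`.
#' @return `path`, invisibly.
#' @export
save_selection <- function(result, weights, path, feature_ids) {
  stopifnot(inherits(result, "SelectionResult"),
            inherits(weights, "ShapleyWeights"))
  if (length(result$selected) == 0L)
    fs_error("shapleyFS_empty_result", "selection result is empty")
  df <- data.frame(
    rank = seq_along(result$selected),
    feature_id = feature_ids[result$selected],
    victory_score = trimws(formatC(result$victory_trace, digits = 17,
                                   format = "g")),
    shapley_weight = trimws(formatC(weights$phi[result$selected], digits = 17,
                                    format = "g")),
    su_relevance = trimws(formatC(result$su_class[result$selected], digits = 17,
                                  format = "g")),
    stringsAsFactors = FALSE)
  ok <- tryCatch({
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    TRUE
  }, error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok) fs_error("shapleyFS_unwritable", "cannot write to %s", path)
  invisible(path)
}

#' Read back a ranked selection TSV
#'
#' @param path file written by [save_selection()].
#' @return data.frame with the five ranked columns, numeric scores restored.
#' @export
load_selection <- function(path) {
  if (!file.exists(path))
    fs_error("shapleyFS_missing_file", "no such file: %s", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  for (col in c("victory_score", "shapley_weight", "su_relevance"))
    df[[col]] <- as.numeric(df[[col]])
  df
}
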