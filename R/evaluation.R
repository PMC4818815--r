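# Measurement harness: stratified k-fold classification metrics and the JC
# subset-stability index under resampling.

#' Confusion-table classification metrics
#'
#' Accuracy is the fraction correct for any number of classes. Precision,
#' recall, and F-measure are computed against `positive_class` and are only
#' meaningful for 2-class problems (they are reported as `NA` otherwise,
#' mirroring common practice of quoting them for binary tasks only). A
#' degenerate denominator (no positive predictions / no positive truth) gives
#' 0 by convention; F is 0 when precision + recall = 0.
#'
#' @param y_true,y_pred label vectors of equal length.
#' @param positive_class which label counts as positive; defaults to the
#'   first factor level.
#' @return list with `accuracy`, `precision`, `recall`, `f_measure`.
#' @export
classification_metrics <- function(y_true, y_pred, positive_class = NULL) {
  y_true <- as.character(y_true)
  y_pred <- as.character(y_pred)
  check_lengths(y_true, y_pred)
  acc <- mean(y_pred == y_true)
  lv <- sort(unique(c(y_true, y_pred)))
  if (length(lv) != 2L)
    return(list(accuracy = acc, precision = NA_real_, recall = NA_real_,
                f_measure = NA_real_))
  pos <- positive_class %||% lv[1L]
  tp <- sum(y_true == pos & y_pred == pos)
  fp <- sum(y_true != pos & y_pred == pos)
  fn <- sum(y_true == pos & y_pred != pos)
  prec <- if (tp + fp == 0L) 0 else tp / (tp + fp)
  rec <- if (tp + fn == 0L) 0 else tp / (tp + fn)
  f <- if (prec + rec == 0) 0 else 2 * prec * rec / (prec + rec)
  list(accuracy = acc, precision = prec, recall = rec, f_measure = f)
}

# stratified fold assignment: within each class, samples are shuffled and
# dealt round-robin into folds. Falls back to unstratified when some class
# has fewer samples than folds.
make_folds <- function(labels, n_folds, seed) {
  labels <- factor(labels)
  n <- length(labels)
  folds <- integer(n)
  rng <- rng_stream(seed)
  if (any(table(labels) < n_folds)) {
    warning("a class has fewer samples than folds; using unstratified folds")
    perm <- rng$sample(n)
    folds[perm] <- rep_len(seq_len(n_folds), n)
  } else {
    for (lv in levels(labels)) {
      idx <- which(labels == lv)
      idx <- idx[rng$sample(length(idx))]
      folds[idx] <- rep_len(seq_len(n_folds), length(idx))
    }
  }
  folds
}

# deterministic RNG scope: evaluates callbacks under a seeded local stream
# without touching the caller's .Random.seed
rng_stream <- function(seed) {
  env <- new.env()
  env$state <- local({
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    set.seed(seed)
    st <- get(".Random.seed", globalenv())
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, globalenv())
    st
  })
  run <- function(expr_fun) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    assign(".Random.seed", env$state, globalenv())
    on.exit({
      env$state <- get(".Random.seed", globalenv())
      if (is.null(old)) rm(".Random.seed", envir = globalenv())
      else assign(".Random.seed", old, globalenv())
    })
    expr_fun()
  }
  list(sample = function(n) run(function() sample.int(n)),
       norm = function(n) run(function() rnorm(n)),
       run = run)
}

#' Stratified k-fold cross-validated classification
#'
#' Trains the given classifier on the selected features only, fold by fold,
#' and averages the per-fold metrics. Deterministic for a fixed seed.
#'
#' @param data an [expression_dataset()].
#' @param selected_features integer column indices to train on.
#' @param spec a [classifier_spec()].
#' @param n_folds number of folds (default 10).
#' @param seed integer seed controlling the fold shuffle.
#' @param positive_class passed to [classification_metrics()].
#' @return A `MetricsReport`: averaged `accuracy`, `precision`, `recall`,
#'   `f_measure`, plus `per_fold` vectors and the fold assignment.
#' @export
cross_validate <- function(data, selected_features, spec = classifier_spec("knn"),
                           n_folds = 10L, seed = 1L, positive_class = NULL) {
  stopifnot(inherits(data, "ExpressionDataset"))
  if (length(selected_features) == 0L)
    fs_error("shapleyFS_empty_set", "selected_features must be non-empty")
  if (n_folds < 2L) fs_error("shapleyFS_bad_k", "n_folds must be >= 2")
  x <- data$matrix[, selected_features, drop = FALSE]
  y <- data$labels
  folds <- make_folds(y, n_folds, seed)
  per_fold <- lapply(seq_len(n_folds), function(f) {
    test <- folds == f
    pred <- fit_predict(spec, x[!test, , drop = FALSE], droplevels(y[!test]),
                        x[test, , drop = FALSE])
    classification_metrics(y[test], pred, positive_class)
  })
  # degenerate folds (one class only, possible when unstratified) give NA
  # precision/recall; average over the informative folds
  avg <- function(field) mean(vapply(per_fold, `[[`, 0, field), na.rm = TRUE)
  structure(list(accuracy = avg("accuracy"),
                 precision = avg("precision"), recall = avg("recall"),
                 f_measure = avg("f_measure"),
                 per_fold = list(accuracy = vapply(per_fold, `[[`, 0, "accuracy")),
                 classifier = spec$name, n_folds = n_folds, folds = folds),
            class = "MetricsReport")
}

#' JC similarity between two equal-size feature subsets
#'
#' JC = (|intersection| + SC) / k. SC credits near-duplicates: each feature in
#' `S_i` but not `S_o` contributes the largest absolute Pearson correlation
#' (computed on the full data matrix) it attains against the features in
#' `S_o` but not `S_i`. Every term is at most 1, so JC stays in [0, 1];
#' identical subsets give exactly 1. Zero-variance features correlate 0 by
#' convention.
#'
#' @param s_i,s_o integer feature-index sets of equal size k.
#' @param data the [expression_dataset()] the subsets were selected from.
#' @return JC in [0, 1].
#' @export
jc_similarity <- function(s_i, s_o, data) {
  if (length(s_i) != length(s_o))
    fs_error("shapleyFS_length_mismatch", "subsets must have equal size")
  k <- length(s_i)
  common <- length(intersect(s_i, s_o))
  only_i <- setdiff(s_i, s_o)
  only_o <- setdiff(s_o, s_i)
  sc <- 0
  if (length(only_i) > 0L && length(only_o) > 0L) {
    a <- data$matrix[, only_i, drop = FALSE]
    b <- data$matrix[, only_o, drop = FALSE]
    cc <- suppressWarnings(abs(cor(a, b)))
    cc[!is.finite(cc)] <- 0
    sc <- sum(apply(cc, 1L, max))
  }
  (common + sc) / k
}

#' Mean and standard deviation of JC stability values
#'
#' @param jc_values non-empty numeric vector of per-resample JC values.
#' @return list with `mean` and `sd` (sample sd; 0 for a single value).
#' @export
mean_stability <- function(jc_values) {
  if (length(jc_values) == 0L) fs_error("shapleyFS_empty_input", "empty input")
  s <- if (length(jc_values) == 1L) 0 else sd(jc_values)
  list(mean = mean(jc_values), sd = s)
}

#' Feature subsets selected from resampled data
#'
#' Runs a selection pipeline once on the full data (the reference subset S_o)
#' and once per training portion of an m-fold partition (the resampled
#' subsets S_i), as in stability estimation by cross-validation resampling.
#'
#' @param data an [expression_dataset()].
#' @param pipeline function(data) returning an integer vector of selected
#'   original-scale feature indices (see [select_features()]).
#' @param n_resamples m, number of folds/resamples (>= 2).
#' @param subset_size k, size every returned subset is truncated to.
#' @param seed controls the fold partition.
#' @return list with `reference` (S_o), `subsets` (list of m S_i), `folds`.
#' @export
resample_subsets <- function(data, pipeline, n_resamples = 10L,
                             subset_size = 20L, seed = 1L) {
  if (n_resamples < 2L) fs_error("shapleyFS_bad_k", "n_resamples must be >= 2")
  take <- function(idx) {
    if (length(idx) < subset_size)
      fs_error("shapleyFS_bad_k",
               "pipeline returned %d features, need subset_size = %d",
               length(idx), subset_size)
    idx[seq_len(subset_size)]
  }
  reference <- take(pipeline(data))
  folds <- make_folds(data$labels, n_resamples, seed)
  subsets <- lapply(seq_len(n_resamples), function(f) {
    keep <- folds != f
    sub <- data
    sub$matrix <- data$matrix[keep, , drop = FALSE]
    sub$labels <- droplevels(data$labels[keep])
    sub$sample_ids <- data$sample_ids[keep]
    take(pipeline(sub))
  })
  list(reference = reference, subsets = subsets, folds = folds)
}

#' Stability of a selection pipeline under resampling
#'
#' Convenience wrapper: resample, compute JC of every resampled subset
#' against the full-data reference, and summarize.
#'
#' @inheritParams resample_subsets
#' @return A `StabilityReport`: `jc_values`, `mean_jc`, `sd_jc`,
#'   `subset_size`, `m`.
#' @export
stability_report <- function(data, pipeline, n_resamples = 10L,
                             subset_size = 20L, seed = 1L) {
  rs <- resample_subsets(data, pipeline, n_resamples, subset_size, seed)
  jc <- vapply(rs$subsets, jc_similarity, 0, s_o = rs$reference, data = data)
  ms <- mean_stability(jc)
  structure(list(jc_values = jc, mean_jc = ms$mean, sd_jc = ms$sd,
                 subset_size = subset_size, m = n_resamples),
            class = "StabilityReport")
}
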