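# End-to-end pipeline: normalize -> univariate prefilter -> Shapley weights
# -> victory-score forward selection, plus the run configuration contract.

#' Default run configuration
#'
#' All tunables of the pipeline and the evaluation harness, as a nested list.
#' Unknown keys are rejected by [resolve_config()] so typos fail loudly.
#'
#' @return named list of configuration defaults.
#' @export
default_config <- function() {
  list(
    normalize = TRUE,
    bins = 5L,
    prefilter = list(method = "fisher", k = 300L),
    shapley = list(utility = "fisher", coalition_size = 2L),
    select = list(n_features = 50L, mode = "shapley_su"),
    eval = list(classifier = "knn", knn_k = 3L, svm_sigma = 20,
                folds = 10L),
    stability = list(m = 10L, subset_size = 20L),
    seed = 1L
  )
}

#' Merge user configuration over the defaults
#'
#' @param config named (possibly nested) list of overrides; unknown keys at
#'   any level raise `shapleyFS_bad_config`.
#' @return fully resolved configuration list.
#' @export
resolve_config <- function(config = list()) {
  merge_into <- function(base, over, path = "") {
    for (key in names(over)) {
      if (!key %in% names(base))
        fs_error("shapleyFS_bad_config", "unknown config key: %s%s", path, key)
      if (is.list(base[[key]]) && !is.null(names(base[[key]]))) {
        base[[key]] <- merge_into(base[[key]], as.list(over[[key]]),
                                  paste0(path, key, "."))
      } else {
        base[[key]] <- over[[key]]
      }
    }
    base
  }
  merge_into(default_config(), as.list(config))
}

#' Run the full selection pipeline
#'
#' Phases: (1) optional z-score normalization and reduction to the top
#' `prefilter$k` features by Fisher ratio or MI; (2) equal-frequency
#' discretization and Shapley weighting of the survivors, with QMI utility
#' equal to each feature's Fisher ratio (or the constant-one ablation);
#' (3) victory-score forward selection of `select$n_features`.
#'
#' @param data an [expression_dataset()].
#' @param config configuration overrides, see [default_config()].
#' @return A `PipelineResult`: `selected` (original-scale column indices, in
#'   selection order), `selected_ids`, `result` (the `SelectionResult` over
#'   the prefiltered space), `weights`, `prefilter` scores, `config`.
#' @export
select_features <- function(data, config = list()) {
  stopifnot(inherits(data, "ExpressionDataset"))
  cfg <- resolve_config(config)
  norm <- zscore_normalize(data, enabled = isTRUE(cfg$normalize))
  k <- min(cfg$prefilter$k, ncol(norm$matrix))
  pf <- rank_and_trim(norm, method = cfg$prefilter$method, k = k,
                      bins = cfg$bins)
  codes <- discretize_matrix(pf$data$matrix, n_bins = cfg$bins)
  utility <- if (identical(cfg$shapley$utility, "constant_one")) {
    rep(1, ncol(codes))
  } else {
    # Fisher-ratio utility per surviving feature, from the normalized data
    fisher_ratio_all(pf$data$matrix, pf$data$labels)
  }
  weights <- compute_all_weights(codes, pf$data$labels, utility,
                                 coalition_size = cfg$shapley$coalition_size)
  n_sel <- min(cfg$select$n_features, ncol(codes))
  result <- forward_select(codes, pf$data$labels, weights,
                           target_count = n_sel, mode = cfg$select$mode)
  selected_orig <- pf$scores$kept[result$selected]
  structure(list(selected = selected_orig,
                 selected_ids = data$feature_ids[selected_orig],
                 result = result, weights = weights,
                 prefilter = pf$scores, config = cfg),
            class = "PipelineResult")
}

#' @export
print.PipelineResult <- function(x, ...) {
  cat(sprintf("PipelineResult: %d features selected (prefilter %s k=%d, utility %s)\n",
              length(x$selected), x$config$prefilter$method,
              x$config$prefilter$k, x$config$shapley$utility))
  cat("top:", paste(utils::head(x$selected_ids, 10L), collapse = ", "), "\n")
  invisible(x)
}

# pipeline closure for resampling/stability: returns original feature indices
pipeline_fun <- function(config = list()) {
  function(data) select_features(data, config)$selected
}
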