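# Phase 1: normalization and univariate filtering (Fisher ratio or MI),
# keeping the top-k features before the game-theoretic phase.

FISHER_CAP <- 1e12   # stands in for +Inf when classes separate with zero variance

#' Z-score normalize each feature column
#'
#' Population (divide-by-n) standard deviation; zero-variance columns are set
#' to all zeros rather than dividing by zero. With `enabled = FALSE` the
#' dataset is returned untouched (some assays, e.g. SRBCT-scale intensities,
#' are conventionally left unnormalized).
#'
#' @param data an [expression_dataset()].
#' @param enabled logical master switch.
#' @return An `ExpressionDataset` with transformed matrix.
#' @export
zscore_normalize <- function(data, enabled = TRUE) {
  stopifnot(inherits(data, "ExpressionDataset"))
  if (!enabled) return(data)
  m <- data$matrix
  n <- nrow(m)
  mu <- colMeans(m)
  sdev <- sqrt(colMeans(m^2) - mu^2)     # population sd
  sdev[sdev <= 0] <- Inf                 # constant columns -> 0 after centering
  m <- sweep(sweep(m, 2L, mu, "-"), 2L, sdev, "/")
  data$matrix <- m
  data
}

fisher_ratio_pair <- function(x1, x2) {
  d2 <- (mean(x1) - mean(x2))^2
  v <- mean((x1 - mean(x1))^2) + mean((x2 - mean(x2))^2)  # population variances
  if (v == 0) return(if (d2 == 0) 0 else FISHER_CAP)
  d2 / v
}

#' Fisher ratio of a single feature
#'
#' Two classes: squared mean difference over the sum of population
#' within-class variances. More than two classes: the mean of the two-class
#' score over all unordered class pairs, so the two-class case is exact.
#' Distinct means with zero within-class variance return the finite cap 1e12
#' instead of infinity (keeps downstream utility products finite).
#'
#' @param feature numeric vector.
#' @param labels class labels (>= 2 classes, each with >= 2 samples).
#' @return Non-negative scalar.
#' @export
fisher_ratio <- function(feature, labels) {
  labels <- factor(labels)
  check_lengths(feature, as.integer(labels))
  if (nlevels(labels) < 2L)
    fs_error("shapleyFS_too_few_classes", "need >= 2 classes")
  if (any(table(labels) < 2L))
    fs_error("shapleyFS_too_few_classes", "every class needs >= 2 samples")
  groups <- split(feature, labels)
  pairs <- combn(length(groups), 2L)
  mean(apply(pairs, 2L, function(p)
    fisher_ratio_pair(groups[[p[1L]]], groups[[p[2L]]])))
}

#' Mutual information of a discretized feature with the class, in bits
#'
#' @param feature numeric vector.
#' @param labels class labels.
#' @param bins number of equal-frequency bins.
#' @export
mi_relevance <- function(feature, labels, bins = 5L) {
  mutual_information(discretize(feature, bins), as_discretized(labels))
}

fisher_ratio_all <- function(mat, labels) {
  # vectorized over features: per-class column means / population variances
  labels <- factor(labels)
  lv <- levels(labels)
  n_c <- length(lv)
  mu <- matrix(0, n_c, ncol(mat))
  v <- matrix(0, n_c, ncol(mat))
  for (c in seq_len(n_c)) {
    sub <- mat[labels == lv[c], , drop = FALSE]
    mu[c, ] <- colMeans(sub)
    v[c, ] <- colMeans(sub^2) - mu[c, ]^2
    v[c, v[c, ] < 0] <- 0                # guard fp round-off
  }
  pairs <- combn(n_c, 2L)
  acc <- numeric(ncol(mat))
  for (p in seq_len(ncol(pairs))) {
    a <- pairs[1L, p]; b <- pairs[2L, p]
    d2 <- (mu[a, ] - mu[b, ])^2
    den <- v[a, ] + v[b, ]
    s <- ifelse(den > 0, d2 / den, ifelse(d2 > 0, FISHER_CAP, 0))
    acc <- acc + s
  }
  acc / ncol(pairs)
}

#' Score all features and keep the top k
#'
#' Ranks features by Fisher ratio or MI relevance (descending, ties broken by
#' ascending original column index) and returns the sub-dataset of the k best
#' together with the full score vector — the Fisher scores double as the QMI
#' utility downstream.
#'
#' @param data an [expression_dataset()].
#' @param method `"fisher"` or `"mutual_information"` (alias `"mi"`).
#' @param k how many features to keep, `1 <= k <= n_features`.
#' @param bins bins for the MI method.
#' @return list with `data` (trimmed `ExpressionDataset`), `scores`
#'   (a `FeatureScoreVector`: full-length `scores`, `method`, `ranking`,
#'   `kept` original indices).
#' @export
rank_and_trim <- function(data, method = c("fisher", "mutual_information", "mi"),
                          k, bins = 5L) {
  stopifnot(inherits(data, "ExpressionDataset"))
  method <- match.arg(method)
  if (method == "mi") method <- "mutual_information"
  n_f <- ncol(data$matrix)
  k <- as.integer(k)
  if (is.na(k) || k < 1L || k > n_f)
    fs_error("shapleyFS_bad_k", "k must be in [1, %d], got %s", n_f, k)
  scores <- if (method == "fisher") {
    fisher_ratio_all(data$matrix, data$labels)
  } else {
    cls <- as_discretized(data$labels)
    apply(data$matrix, 2L, function(col)
      mutual_information(discretize(col, bins), cls))
  }
  ranking <- order(-scores, seq_len(n_f))
  kept <- ranking[seq_len(k)]
  sub <- data
  sub$matrix <- data$matrix[, kept, drop = FALSE]
  sub$feature_ids <- data$feature_ids[kept]
  score_vec <- structure(list(scores = scores, method = method,
                              ranking = ranking, kept = kept),
                         class = "FeatureScoreVector")
  list(data = sub, scores = score_vec)
}
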