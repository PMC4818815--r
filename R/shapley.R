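# Phase 2: features are players in a cooperative game. The payoff of adding
# feature i to a coalition K is binary: 1 when i does not lower K's relevance
# to the class and is interdependent (conditioning on i raises the class
# information of f_j above its qualitative marginal) with at least half of K.
# The Shapley value averages that payoff over all coalitions of the
# configured size.

#' Precompute the pairwise information quantities the game consumes
#'
#' Builds, once, everything coalition evaluation needs: `qmi_class[j]` =
#' QMI(f_j; class) under the chosen utility and `cmi_given[i, j]` =
#' CMI(f_j; class | f_i) for all ordered pairs (an O(n^2) pass implemented in
#' C++; the coalition loops afterwards are pure table lookups).
#'
#' @param codes integer code matrix from [discretize_matrix()] (samples x
#'   features).
#' @param class a `DiscretizedFeature` (or label vector) for the class.
#' @param utility either a single [utility_spec()] applied to every feature,
#'   or a numeric vector of per-feature Fisher-ratio utilities.
#' @return A `PairwiseCache`: list with `qmi_class`, `cmi_given`, `mi_class`,
#'   `utility_values`, `n_features`.
#' @export
build_pairwise_cache <- function(codes, class, utility = utility_spec("constant_one")) {
  if (!is.matrix(codes)) fs_error("shapleyFS_bad_matrix", "codes must be a matrix")
  n_f <- ncol(codes)
  if (n_f < 2L) fs_error("shapleyFS_too_few_features", "need >= 2 features")
  cls <- codes_of(class)
  check_lengths(codes[, 1L], cls)
  u <- if (inherits(utility, "UtilitySpec")) {
    if (utility$mode == "constant_one") rep(1, n_f)
    else rep(utility$per_feature_value, n_f)
  } else {
    as.numeric(utility)
  }
  if (length(u) != n_f || any(!is.finite(u)) || any(u < 0))
    fs_error("shapleyFS_bad_utility",
             "need one finite non-negative utility per feature")
  raw <- pairwise_cache_cpp(codes, as.integer(cls))
  structure(list(qmi_class = raw$mi * u,
                 mi_class = raw$mi,
                 cmi_given = raw$cmi_given,
                 utility_values = u,
                 n_features = n_f),
            class = "PairwiseCache")
}

#' Interdependence index psi(i, j)
#'
#' 1 when conditioning on f_i strictly increases f_j's class information above
#' its qualitative marginal: CMI(f_j; class | f_i) > QMI(f_j; class).
#' Equality counts as redundancy (psi = 0).
#'
#' @param i,j distinct feature indices.
#' @param cache a [build_pairwise_cache()] result.
#' @return 0 or 1.
#' @export
interdependence_index <- function(i, j, cache) {
  if (i == j) fs_error("shapleyFS_bad_index", "i and j must differ")
  as.integer(cache$cmi_given[i, j] > cache$qmi_class[j])
}

#' Relevance of a feature set to the class
#'
#' D(K, class) = mean over j in K of QMI(f_j; class).
#'
#' @param K non-empty integer vector of feature indices.
#' @param cache a `PairwiseCache`.
#' @export
set_relevance <- function(K, cache) {
  if (length(K) == 0L) fs_error("shapleyFS_empty_set", "K must be non-empty")
  mean(cache$qmi_class[K])
}

#' Change in set relevance when conditioning on a candidate feature
#'
#' mean over j in K of [ CMI(f_j; class | f_i) - QMI(f_j; class) ]: positive
#' when feature i on average raises the class information of K's members.
#'
#' @param K non-empty set of feature indices, not containing `i`.
#' @param i candidate feature index.
#' @param cache a `PairwiseCache`.
#' @export
relevance_change <- function(K, i, cache) {
  if (length(K) == 0L) fs_error("shapleyFS_empty_set", "K must be non-empty")
  if (i %in% K) fs_error("shapleyFS_bad_index", "i must not be in K")
  mean(cache$cmi_given[i, K] - cache$qmi_class[K])
}

#' Binary coalition payoff Delta_i(K)
#'
#' 1 iff the relevance change of K under i is >= 0 AND i is interdependent
#' with at least half of K's members (sum of psi(i, j) >= |K| / 2).
#'
#' @inheritParams relevance_change
#' @return 0 or 1.
#' @export
coalition_payoff <- function(K, i, cache) {
  if (relevance_change(K, i, cache) < 0) return(0L)
  psi_sum <- sum(cache$cmi_given[i, K] > cache$qmi_class[K])
  as.integer(2L * psi_sum >= length(K))
}

#' Shapley value of one feature
#'
#' phi_i = sum over all coalitions K of size k drawn from the other features
#' of Delta_i(K) * k! (n-k-1)! / n!. Bounded by 1/n (attained when every
#' coalition qualifies). Exact enumeration; the C(n-1, k) subsets are walked
#' in C++.
#'
#' @param i feature index.
#' @param cache a `PairwiseCache`.
#' @param coalition_size coalition size k, `1 <= k <= n - 1`.
#' @export
shapley_value <- function(i, cache, coalition_size = 2L) {
  compute_all_weights_from_cache(cache, coalition_size)$phi[i]
}

compute_all_weights_from_cache <- function(cache, coalition_size = 2L) {
  n <- cache$n_features
  k <- as.integer(coalition_size)
  if (k < 1L || k >= n)
    fs_error("shapleyFS_bad_coalition",
             "coalition_size must be in [1, %d], got %d", n - 1L, k)
  if (k > 3L)
    warning(sprintf(
      "coalition_size = %d enumerates C(n-1, %d) subsets per feature; this is expensive beyond toy sizes",
      k, k))
  psi <- matrix(0L, n, n)
  d <- sweep(cache$cmi_given, 2L, cache$qmi_class, "-")
  psi[] <- as.integer(cache$cmi_given > matrix(cache$qmi_class, n, n, byrow = TRUE))
  diag(psi) <- 0L; diag(d) <- 0
  phi <- shapley_phi_cpp(psi, d, k)
  structure(list(phi = phi, coalition_size = k, n_features = n),
            class = "ShapleyWeights")
}

#' Shapley weights for every feature
#'
#' End-to-end phase 2: discretized features + class + utility in, one Shapley
#' weight per feature out. Deterministic for fixed input.
#'
#' @param codes integer code matrix (samples x features) from
#'   [discretize_matrix()].
#' @param class class labels or `DiscretizedFeature`.
#' @param utility per-feature utility vector or a [utility_spec()].
#' @param coalition_size coalition size (default 2: all two-member subsets).
#' @return A `ShapleyWeights`: list with `phi`, `coalition_size`,
#'   `n_features`, and the `cache` it was built from.
#' @export
compute_all_weights <- function(codes, class,
                                utility = utility_spec("constant_one"),
                                coalition_size = 2L) {
  if (ncol(codes) < 3L)
    fs_error("shapleyFS_too_few_features",
             "need >= 3 features for a size-%d coalition game", coalition_size)
  cache <- build_pairwise_cache(codes, class, utility)
  w <- compute_all_weights_from_cache(cache, coalition_size)
  w$cache <- cache
  w
}

#' @export
print.ShapleyWeights <- function(x, ...) {
  cat(sprintf("ShapleyWeights: %d features, coalition size %d, phi in [%.4g, %.4g]\n",
              x$n_features, x$coalition_size, min(x$phi), max(x$phi)))
  invisible(x)
}
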