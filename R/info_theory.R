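# Discretization and plug-in information-theoretic estimators. Everything is
# in bits (log base 2) with the 0*log(0) = 0 convention, on empirical
# contingency tables of integer-coded variables.

#' Discretize a continuous feature
#'
#' `equal_frequency` (the package default, B = 5) assigns codes by sorted
#' position so bins hold ceiling(n/B) +/- 1 samples; ties are ordered by value
#' then original index, so heavily tied values may straddle a bin boundary
#' (bin counts stay balanced). A constant vector collapses to a single
#' occupied bin. `equal_width` cuts the observed range into B equal intervals.
#'
#' @param values finite numeric vector.
#' @param n_bins number of bins, B >= 1.
#' @param strategy `"equal_frequency"` or `"equal_width"`.
#' @return A `DiscretizedFeature`: list with integer `codes` in `0..B-1`,
#'   `n_bins`, and numeric `bin_edges` (empty for degenerate/categorical
#'   sources).
#' @export
discretize <- function(values, n_bins = 5L,
                       strategy = c("equal_frequency", "equal_width")) {
  strategy <- match.arg(strategy)
  if (!is.numeric(values) || !all(is.finite(values)))
    fs_error("shapleyFS_nonfinite", "values must be finite numeric")
  n <- length(values)
  if (n < 1L) fs_error("shapleyFS_empty_input", "empty input")
  n_bins <- as.integer(n_bins)
  if (is.na(n_bins) || n_bins < 1L)
    fs_error("shapleyFS_bad_bins", "n_bins must be >= 1")
  B <- min(n_bins, n)
  if (diff(range(values)) == 0) {      # constant: one occupied bin
    return(new_discretized(integer(n), B, numeric(0)))
  }
  if (strategy == "equal_frequency") {
    ord <- order(values, seq_len(n))
    sizes <- rep(n %/% B, B)
    extra <- n %% B
    if (extra > 0L) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
    codes <- integer(n)
    codes[ord] <- rep.int(seq_len(B) - 1L, sizes)
    edges <- values[ord][cumsum(sizes)[-B]]
  } else {
    rng <- range(values)
    edges <- seq(rng[1L], rng[2L], length.out = B + 1L)[-c(1L, B + 1L)]
    codes <- findInterval(values, edges, left.open = TRUE)
  }
  new_discretized(as.integer(codes), B, as.numeric(edges))
}

new_discretized <- function(codes, n_bins, bin_edges) {
  structure(list(codes = codes, n_bins = as.integer(n_bins),
                 bin_edges = bin_edges),
            class = "DiscretizedFeature")
}

#' Treat categorical codes (e.g. class labels) as an already-discrete variable
#' @param x factor, integer, or character vector.
#' @return A `DiscretizedFeature` with one state per observed level.
#' @export
as_discretized <- function(x) {
  if (inherits(x, "DiscretizedFeature")) return(x)
  f <- factor(x)
  new_discretized(as.integer(f) - 1L, nlevels(f), numeric(0))
}

codes_of <- function(x) {
  if (inherits(x, "DiscretizedFeature")) x$codes else as_discretized(x)$codes
}

check_lengths <- function(...) {
  ls <- vapply(list(...), length, 1L)
  if (length(unique(ls)) != 1L)
    fs_error("shapleyFS_length_mismatch",
             "inputs have different lengths: %s", paste(ls, collapse = ", "))
}

# probability vector over occupied cells of a joint coding
joint_p <- function(...) {
  args <- list(...)
  idx <- args[[1L]] - min(args[[1L]])
  mult <- max(idx) + 1L
  if (length(args) > 1L) for (a in args[-1L]) {
    a <- a - min(a)
    idx <- idx + mult * a
    mult <- mult * (max(a) + 1L)
  }
  counts <- tabulate(idx + 1L, nbins = mult)
  counts[counts > 0L] / length(idx)
}

#' Shannon entropy of a discretized variable, in bits
#'
#' @param x a `DiscretizedFeature` (or any vector coercible by
#'   [as_discretized()]).
#' @return H(X) = -sum p log2 p over occupied states; 0 for a constant.
#' @export
entropy <- function(x) {
  cx <- codes_of(x)
  if (length(cx) == 0L) fs_error("shapleyFS_empty_input", "empty input")
  p <- joint_p(cx)
  -sum(p * log2(p))
}

#' Mutual information between two discretized variables, in bits
#'
#' Plug-in estimate from the empirical joint table:
#' MI(X;Y) = sum p(x,y) log2( p(x,y) / (p(x) p(y)) ), which is symmetric,
#' non-negative, and bounded by min(H(X), H(Y)).
#'
#' @param x,y `DiscretizedFeature`s of equal length.
#' @export
mutual_information <- function(x, y) {
  cx <- codes_of(x); cy <- codes_of(y)
  check_lengths(cx, cy)
  hx <- entropy(x); hy <- entropy(y)
  hxy <- -sum(joint_p(cx, cy) * log2(joint_p(cx, cy)))
  mi <- hx + hy - hxy
  max(mi, 0)
}

#' Specify the utility used by qualitative mutual information
#'
#' QMI multiplies each joint-probability term of MI by a utility U. Here U is
#' constant per feature: in `fisher` mode it is the feature's Fisher ratio, so
#' QMI(f; class) = FR(f) * MI(f; class); `constant_one` mode reduces QMI to
#' plain MI (the ablation that mimics plain-MI cooperative-game selection).
#'
#' @param mode `"fisher"` or `"constant_one"`.
#' @param per_feature_value the finite non-negative utility constant (ignored
#'   for `constant_one`).
#' @return A `UtilitySpec`.
#' @export
utility_spec <- function(mode = c("fisher", "constant_one"),
                         per_feature_value = 1) {
  mode <- match.arg(mode)
  if (mode == "constant_one") per_feature_value <- 1
  if (!is.finite(per_feature_value) || per_feature_value < 0)
    fs_error("shapleyFS_bad_utility",
             "utility value must be finite and >= 0")
  structure(list(mode = mode, per_feature_value = per_feature_value),
            class = "UtilitySpec")
}

#' Qualitative mutual information
#'
#' MI with each cell term scaled by the utility; with a per-feature-constant
#' utility this is exactly `per_feature_value * MI(x; y)`.
#'
#' @inheritParams mutual_information
#' @param utility a [utility_spec()].
#' @export
qualitative_mutual_information <- function(x, y, utility) {
  stopifnot(inherits(utility, "UtilitySpec"))
  u <- if (utility$mode == "constant_one") 1 else utility$per_feature_value
  u * mutual_information(x, y)
}

#' Conditional mutual information CMI(X; Y | Z), in bits
#'
#' Plug-in estimate sum p(x,y,z) log2( p(x,y|z) / (p(x|z) p(y|z)) ), computed
#' as H(X,Z) + H(Y,Z) - H(Z) - H(X,Y,Z). Provably >= 0 for plug-in
#' estimates; tiny negative round-off is clamped to zero so the
#' redundancy/interdependence comparisons stay stable.
#'
#' @param x,y,z `DiscretizedFeature`s of equal length.
#' @export
conditional_mutual_information <- function(x, y, z) {
  cx <- codes_of(x); cy <- codes_of(y); cz <- codes_of(z)
  check_lengths(cx, cy, cz)
  h <- function(...) { p <- joint_p(...); -sum(p * log2(p)) }
  cmi <- h(cx, cz) + h(cy, cz) - h(cz) - h(cx, cy, cz)
  max(cmi, 0)
}

#' Symmetric uncertainty SU(f, class)
#'
#' SU = 2 MI(f; class) / (H(f) + H(class)), a normalized relevance in [0, 1].
#' A constant feature has SU 0 by convention; a constant class is an error.
#'
#' @param f,class `DiscretizedFeature`s of equal length.
#' @export
symmetric_uncertainty <- function(f, class) {
  cf <- codes_of(f); cc <- codes_of(class)
  check_lengths(cf, cc)
  hc <- entropy(class)
  if (hc == 0) fs_error("shapleyFS_constant_class", "class must not be constant")
  hf <- entropy(f)
  if (hf == 0) return(0)
  su <- 2 * mutual_information(f, class) / (hf + hc)
  min(max(su, 0), 1)
}

#' Discretize every column of an expression matrix
#'
#' @param mat numeric samples x features matrix.
#' @param n_bins,strategy passed to [discretize()].
#' @return integer matrix of codes (same shape), attribute `n_bins`.
#' @export
discretize_matrix <- function(mat, n_bins = 5L,
                              strategy = "equal_frequency") {
  codes <- vapply(seq_len(ncol(mat)), function(j)
    discretize(mat[, j], n_bins, strategy)$codes, integer(nrow(mat)))
  codes <- matrix(codes, nrow = nrow(mat),
                  dimnames = list(rownames(mat), colnames(mat)))
  attr(codes, "n_bins") <- as.integer(n_bins)
  codes
}
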