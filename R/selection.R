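# Phase 3: greedy forward search on the victory score
# V(f) = (1 + w_hat(f)) * g(f), where w_hat is the min-max normalized Shapley
# weight and g is symmetric-uncertainty relevance minus mean SU redundancy
# against the already-selected set.

#' Relevance/redundancy criterion g(f)
#'
#' With nothing selected yet, g(f) = SU(f; class). Afterwards the mean SU
#' between f and each already-selected feature is subtracted
#' (minimum-redundancy-maximum-relevance style, with SU as the measure), so g
#' can go negative for features that mostly duplicate the current set.
#'
#' @param f candidate feature index (not in `selected`).
#' @param selected integer vector of already-selected feature indices.
#' @param su_class numeric vector, SU(f_j; class) for every feature.
#' @param su_pairs matrix lookup with `su_pairs[f, s]` = SU(f_f; f_s); only
#'   rows/columns touching `selected` are read.
#' @export
criterion_g <- function(f, selected, su_class, su_pairs = NULL) {
  if (f %in% selected) fs_error("shapleyFS_bad_index", "feature already selected")
  if (length(selected) == 0L) return(su_class[f])
  su_class[f] - mean(su_pairs[f, selected])
}

#' Victory score V(f)
#'
#' V(f) = (1 + w_hat(f)) * g(f). `w_hat` is phi min-max normalized to [0, 1]
#' (all-equal phi gives w_hat = 0 for everyone, so V degrades to pure g
#' ranking). The `1 +` keeps candidates with phi = 0 alive: raw Shapley
#' weights are frequently zero for many features and a pure product would
#' annihilate them.
#'
#' @param f feature index.
#' @param g the criterion value for f.
#' @param weights a `ShapleyWeights`.
#' @export
victory_score <- function(f, g, weights) {
  (1 + normalize_phi(weights$phi)[f]) * g
}

normalize_phi <- function(phi) {
  rng <- range(phi)
  if (rng[2L] == rng[1L]) return(rep(0, length(phi)))
  (phi - rng[1L]) / (rng[2L] - rng[1L])
}

#' Greedy forward selection by victory score
#'
#' At each step computes g then V for every unselected feature and appends the
#' argmax; ties go to the larger Shapley weight, then the smaller feature
#' index. Fully deterministic.
#'
#' @param codes integer code matrix (samples x features) from
#'   [discretize_matrix()].
#' @param class class labels or `DiscretizedFeature`.
#' @param weights a `ShapleyWeights` over the same features.
#' @param target_count how many features to select (clamped to the number of
#'   features with a warning).
#' @param mode victory combination: `"shapley_su"` (default, `(1+w)*g`),
#'   `"product"` (`w*g`), or `"su_only"` (ignore weights) — the latter two are
#'   sensitivity switches.
#' @return A `SelectionResult`: `selected` (ordered indices), `victory_trace`,
#'   `g_trace`, `su_class`, `target_count`.
#' @export
forward_select <- function(codes, class, weights, target_count = 50L,
                           mode = c("shapley_su", "product", "su_only")) {
  mode <- match.arg(mode)
  stopifnot(inherits(weights, "ShapleyWeights"))
  n <- ncol(codes)
  if (n != weights$n_features)
    fs_error("shapleyFS_bad_matrix", "weights cover %d features, data has %d",
             weights$n_features, n)
  target_count <- as.integer(target_count)
  if (target_count < 1L) fs_error("shapleyFS_bad_k", "target_count must be >= 1")
  if (target_count > n) {
    warning(sprintf("target_count %d exceeds %d features; clamped", target_count, n))
    target_count <- n
  }
  cls <- as_discretized(class)
  feats <- lapply(seq_len(n), function(j) new_discretized(codes[, j],
                                                          max(codes[, j]) + 1L,
                                                          numeric(0)))
  su_class <- vapply(feats, symmetric_uncertainty, 0, class = cls)
  w_hat <- switch(mode,
                  shapley_su = 1 + normalize_phi(weights$phi),
                  product = normalize_phi(weights$phi),
                  su_only = rep(1, n))
  su_pairs <- matrix(NA_real_, n, n)
  selected <- integer(0)
  v_trace <- g_trace <- numeric(0)
  red_sum <- numeric(n)                  # running sum of SU(f, s) over selected
  remaining <- rep(TRUE, n)
  for (step in seq_len(target_count)) {
    cand <- which(remaining)
    g <- if (length(selected) == 0L) su_class[cand]
         else su_class[cand] - red_sum[cand] / length(selected)
    v <- w_hat[cand] * g
    best <- cand[order(-v, -weights$phi[cand], cand)[1L]]
    selected <- c(selected, best)
    v_trace <- c(v_trace, v[match(best, cand)])
    g_trace <- c(g_trace, g[match(best, cand)])
    remaining[best] <- FALSE
    if (step < target_count) {
      idx <- which(remaining)
      su_new <- if (entropy(feats[[best]]) == 0) rep(0, length(idx))
                else vapply(idx, function(j) {
                  symmetric_uncertainty(feats[[j]], feats[[best]])
                }, 0)
      su_pairs[idx, best] <- su_pairs[best, idx] <- su_new
      red_sum[idx] <- red_sum[idx] + su_new
    }
  }
  structure(list(selected = selected, victory_trace = v_trace,
                 g_trace = g_trace, su_class = su_class,
                 target_count = target_count, mode = mode),
            class = "SelectionResult")
}

#' @export
print.SelectionResult <- function(x, ...) {
  cat(sprintf("SelectionResult: %d features (mode %s)\n",
              length(x$selected), x$mode))
  print(utils::head(data.frame(rank = seq_along(x$selected),
                               feature = x$selected,
                               victory = x$victory_trace,
                               g = x$g_trace), 10L))
  invisible(x)
}
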