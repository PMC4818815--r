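# Seeded generator of microarray-like data with planted ground truth:
# a handful of class-informative features, correlated redundant copies of
# them, and a large block of pure noise — the regime of real expression
# panels (thousands of features, tens-to-hundreds of samples).

#' Describe a synthetic expression dataset
#'
#' @param n_samples number of samples.
#' @param n_classes number of (near-)balanced classes.
#' @param n_informative features with class-dependent means.
#' @param n_redundant_per_informative correlated copies per informative
#'   feature.
#' @param n_noise class-independent standard-normal features.
#' @param effect_size separation of adjacent class means in within-class sd
#'   units.
#' @param redundancy_corr target population correlation between a redundant
#'   copy and its parent, in (0, 1].
#' @param seed integer seed; generation uses Mersenne-Twister and never
#'   touches the caller's RNG state.
#' @return A `SyntheticSpec`.
#' @export
synthetic_spec <- function(n_samples = 100L, n_classes = 2L,
                           n_informative = 10L,
                           n_redundant_per_informative = 4L,
                           n_noise = 1950L, effect_size = 2,
                           redundancy_corr = 0.9, seed = 1234L) {
  stopifnot(n_samples >= 4L, n_classes >= 2L, n_informative >= 0L,
            n_redundant_per_informative >= 0L, n_noise >= 0L,
            effect_size >= 0, redundancy_corr > 0, redundancy_corr <= 1)
  if (effect_size > 0 && n_informative < 1L)
    fs_error("shapleyFS_bad_spec", "effect_size > 0 needs n_informative >= 1")
  structure(list(n_samples = as.integer(n_samples),
                 n_classes = as.integer(n_classes),
                 n_informative = as.integer(n_informative),
                 n_redundant_per_informative = as.integer(n_redundant_per_informative),
                 n_noise = as.integer(n_noise),
                 effect_size = effect_size,
                 redundancy_corr = redundancy_corr,
                 seed = as.integer(seed)),
            class = "SyntheticSpec")
}

#' Generate a synthetic expression dataset with known ground truth
#'
#' Informative features are unit-variance Gaussians whose class means are
#' equally spaced and centred, with adjacent-class separation `effect_size`
#' (for two classes this is the exact two-point "simplex" +/- effect/2; with
#' more classes, univariate means cannot be mutually equidistant, so adjacent
#' spacing is held constant instead). Each redundant feature is its parent
#' plus Gaussian noise scaled so the empirical correlation matches
#' `redundancy_corr` (`corr = 1` gives an exact copy). Noise features are iid
#' standard normal. Fully reproducible from `spec$seed`.
#'
#' @param spec a [synthetic_spec()].
#' @return list with `data` (an [expression_dataset()]) and `ground_truth`
#'   (index sets `informative`, `redundant`, `noise`, and `group` mapping
#'   every signal feature to its planted group).
#' @export
generate_synthetic <- function(spec = synthetic_spec()) {
  stopifnot(inherits(spec, "SyntheticSpec"))
  rng <- rng_stream(spec$seed)
  n <- spec$n_samples; C <- spec$n_classes
  sizes <- rep(n %/% C, C)
  sizes[seq_len(n %% C)] <- sizes[seq_len(n %% C)] + 1L
  labels <- factor(rep(paste0("class", seq_len(C)), sizes))
  centers <- (seq_len(C) - (C + 1) / 2) * spec$effect_size
  p_inf <- spec$n_informative
  p_red <- p_inf * spec$n_redundant_per_informative
  p_noise <- spec$n_noise
  p <- p_inf + p_red + p_noise
  mat <- matrix(0, n, p)
  rng$run(function() {
    if (p_inf > 0L) {
      mat[, seq_len(p_inf)] <<- matrix(rnorm(n * p_inf), n, p_inf) +
        centers[as.integer(labels)]
    }
    col <- p_inf
    rho <- spec$redundancy_corr
    for (g in seq_len(p_inf)) {
      for (r in seq_len(spec$n_redundant_per_informative)) {
        col <- col + 1L
        base <- mat[, g]
        if (rho >= 1) {
          mat[, col] <<- base
        } else {
          v <- mean((base - mean(base))^2)
          s <- sqrt(v * (1 - rho^2) / rho^2)
          mat[, col] <<- base + rnorm(n, sd = s)
        }
      }
    }
    if (p_noise > 0L)
      mat[, (p_inf + p_red + 1L):p] <<- matrix(rnorm(n * p_noise), n, p_noise)
    invisible(NULL)
  })
  ids <- c(if (p_inf > 0L) sprintf("INF%03d", seq_len(p_inf)),
           if (p_red > 0L) sprintf("RED%03d_%d",
                                   rep(seq_len(p_inf),
                                       each = spec$n_redundant_per_informative),
                                   rep(seq_len(spec$n_redundant_per_informative),
                                       p_inf)),
           if (p_noise > 0L) sprintf("NOI%05d", seq_len(p_noise)))
  data <- expression_dataset(mat, labels, feature_ids = ids)
  group <- integer(0)
  if (p_inf > 0L)
    group <- c(seq_len(p_inf),
               rep(seq_len(p_inf), each = spec$n_redundant_per_informative))
  list(data = data,
       ground_truth = list(
         informative = seq_len(p_inf),
         redundant = if (p_red > 0L) p_inf + seq_len(p_red) else integer(0),
         noise = if (p_noise > 0L) (p_inf + p_red) + seq_len(p_noise) else integer(0),
         group = group))
}

#' The canonical built-in test fixture
#'
#' 100 samples, 2 balanced classes, 10 informative features, 40 redundant
#' copies (4 per informative, correlation 0.9), 1950 noise features, effect
#' size 2 within-class sd, seed 1234 — a desk-scale analogue of the smallest
#' published microarray panels (a few thousand features, under a hundred
#' samples).
#'
#' @param seed override the fixture seed (default 1234).
#' @return As [generate_synthetic()].
#' @export
default_fixture <- function(seed = 1234L) {
  generate_synthetic(synthetic_spec(seed = seed))
}
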