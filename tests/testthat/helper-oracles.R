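# Independent brute-force oracles. Everything here builds explicit
# contingency tables and sums cell by cell — deliberately naive, and kept
# structurally different from the package's entropy-decomposition estimators.

oracle_entropy <- function(codes) {
  p <- as.numeric(table(codes)) / length(codes)
  -sum(p * log2(p))
}

oracle_mi <- function(x, y, u = 1) {
  n <- length(x)
  tab <- table(x, y)
  px <- rowSums(tab) / n
  py <- colSums(tab) / n
  total <- 0
  for (i in seq_len(nrow(tab))) for (j in seq_len(ncol(tab))) {
    p <- tab[i, j] / n
    if (p > 0) total <- total + u * p * log2(p / (px[i] * py[j]))
  }
  unname(total)
}

oracle_cmi <- function(x, y, z) {
  n <- length(x)
  tab <- table(x, y, z)
  txz <- table(x, z); tyz <- table(y, z); tz <- table(z)
  total <- 0
  for (i in seq_len(dim(tab)[1])) for (j in seq_len(dim(tab)[2]))
    for (k in seq_len(dim(tab)[3])) {
      c_xyz <- tab[i, j, k]
      if (c_xyz > 0) {
        # p log2( p(x,y|z) / (p(x|z) p(y|z)) ) with counts
        total <- total + (c_xyz / n) *
          log2((c_xyz * tz[k]) / (txz[i, k] * tyz[j, k]))
      }
    }
  unname(total)
}

oracle_su <- function(f, cls) {
  hf <- oracle_entropy(f)
  if (hf == 0) return(0)
  2 * oracle_mi(f, cls) / (hf + oracle_entropy(cls))
}

# exhaustive Shapley enumeration straight from the definitions: every size-k
# subset of the other features, payoff re-derived from the cache entries.
oracle_shapley <- function(cache, coalition_size) {
  n <- cache$n_features
  k <- coalition_size
  weight <- factorial(k) * factorial(n - k - 1) / factorial(n)
  vapply(seq_len(n), function(i) {
    others <- setdiff(seq_len(n), i)
    subsets <- combn(others, k)
    count <- 0L
    for (s in seq_len(ncol(subsets))) {
      K <- subsets[, s]
      dbar <- mean(cache$cmi_given[i, K] - cache$qmi_class[K])
      psi_sum <- sum(cache$cmi_given[i, K] > cache$qmi_class[K])
      if (dbar >= 0 && psi_sum >= k / 2) count <- count + 1L
    }
    count * weight
  }, 0)
}

fake_cache <- function(qmi, cmi) {
  structure(list(qmi_class = qmi, mi_class = qmi, cmi_given = cmi,
                 utility_values = rep(1, length(qmi)),
                 n_features = length(qmi)),
            class = "PairwiseCache")
}

random_cache <- function(n) {
  cmi <- matrix(runif(n * n, 0, 1), n, n)
  diag(cmi) <- 0
  fake_cache(qmi = runif(n, 0, 1), cmi = cmi)
}

# small labelled dataset helper
tiny_dataset <- function(n = 20, p = 5, seed = 42) {
  withr::with_seed(seed, {
    m <- matrix(rnorm(n * p), n, p)
    expression_dataset(m, labels = rep(c("a", "b"), length.out = n))
  })
}

# balanced XOR triple: class = f1 XOR f2
xor_codes <- function(reps = 2L) {
  f1 <- rep(c(0L, 0L, 1L, 1L), reps)
  f2 <- rep(c(0L, 1L, 0L, 1L), reps)
  list(codes = cbind(f1, f2), class = bitwXor(f1, f2))
}
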