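# Minimal internal classifiers for the evaluation harness. None of the usual
# providers (class, e1071, rpart, kernlab) are assumed to be installed, so
# the four reference learners are implemented directly. They are an
# evaluation harness, not a contribution: exact brute-force KNN, closed-form
# Gaussian naive Bayes, a greedy Gini binary tree, and a least-squares SVM
# (kernel ridge on +/-1 targets) with a Gaussian kernel, one-vs-rest for
# multiclass.

#' Specify the classifier used by the evaluation harness
#'
#' Defaults follow common microarray practice: KNN with K = 3, Gaussian-kernel
#' SVM with kernel width sigma = 20, Gaussian naive Bayes, CART-style tree.
#'
#' @param name one of `"knn"`, `"svm_rbf"`, `"naive_bayes"`, `"cart"`.
#' @param knn_k neighbours for KNN.
#' @param svm_sigma Gaussian kernel width sigma in
#'   K(x, y) = exp(-||x-y||^2 / (2 sigma^2)).
#' @param svm_lambda ridge penalty of the least-squares SVM.
#' @param cart_min_split minimum node size the tree will split.
#' @param cart_max_depth maximum tree depth.
#' @return A `ClassifierSpec`.
#' @export
classifier_spec <- function(name = c("knn", "svm_rbf", "naive_bayes", "cart"),
                            knn_k = 3L, svm_sigma = 20, svm_lambda = 0.1,
                            cart_min_split = 5L, cart_max_depth = 10L) {
  name <- match.arg(name)
  structure(list(name = name, knn_k = as.integer(knn_k),
                 svm_sigma = svm_sigma, svm_lambda = svm_lambda,
                 cart_min_split = as.integer(cart_min_split),
                 cart_max_depth = as.integer(cart_max_depth)),
            class = "ClassifierSpec")
}

fit_predict <- function(spec, x_train, y_train, x_test) {
  switch(spec$name,
         knn = knn_predict(x_train, y_train, x_test, spec$knn_k),
         naive_bayes = gnb_predict(x_train, y_train, x_test),
         svm_rbf = lssvm_predict(x_train, y_train, x_test,
                                 spec$svm_sigma, spec$svm_lambda),
         cart = cart_predict(x_train, y_train, x_test,
                             spec$cart_min_split, spec$cart_max_depth))
}

knn_predict <- function(x_train, y_train, x_test, k) {
  k <- min(k, nrow(x_train))
  d2 <- outer(rowSums(x_test^2), rowSums(x_train^2), "+") -
    2 * tcrossprod(x_test, x_train)
  lv <- levels(y_train)
  pred <- apply(d2, 1L, function(row) {
    nn <- order(row, seq_along(row))[seq_len(k)]   # deterministic distance ties
    votes <- tabulate(as.integer(y_train[nn]), nbins = length(lv))
    lv[which.max(votes)]                            # vote ties: first level
  })
  factor(pred, levels = lv)
}

gnb_predict <- function(x_train, y_train, x_test) {
  lv <- levels(y_train)
  eps <- 1e-9
  scores <- sapply(lv, function(cl) {
    sub <- x_train[y_train == cl, , drop = FALSE]
    mu <- colMeans(sub)
    v <- apply(sub, 2L, var) + eps
    prior <- log(nrow(sub) / nrow(x_train))
    prior - 0.5 * colSums((t(x_test) - mu)^2 / v) - 0.5 * sum(log(2 * pi * v))
  })
  scores <- matrix(scores, nrow = nrow(x_test))
  factor(lv[max.col(scores, ties.method = "first")], levels = lv)
}

rbf_kernel <- function(a, b, sigma) {
  d2 <- outer(rowSums(a^2), rowSums(b^2), "+") - 2 * tcrossprod(a, b)
  exp(-pmax(d2, 0) / (2 * sigma^2))
}

lssvm_predict <- function(x_train, y_train, x_test, sigma, lambda) {
  lv <- levels(y_train)
  K <- rbf_kernel(x_train, x_train, sigma)
  Kt <- rbf_kernel(x_test, x_train, sigma)
  A <- K + diag(lambda, nrow(K))
  scores <- sapply(lv, function(cl) {
    y <- ifelse(y_train == cl, 1, -1)
    Kt %*% solve(A, y)
  })
  scores <- matrix(scores, nrow = nrow(x_test))
  factor(lv[max.col(scores, ties.method = "first")], levels = lv)
}

# greedy binary tree on Gini impurity
cart_fit <- function(x, y, min_split, max_depth) {
  lv <- levels(y)
  grow <- function(idx, depth) {
    yi <- y[idx]
    counts <- tabulate(as.integer(yi), nbins = length(lv))
    leaf <- list(leaf = TRUE, class = lv[which.max(counts)])
    if (depth >= max_depth || length(idx) < min_split ||
        length(unique(yi)) == 1L) return(leaf)
    best <- NULL; best_gini <- Inf
    n <- length(idx)
    for (j in seq_len(ncol(x))) {
      xs <- x[idx, j]
      cuts <- unique(xs)
      if (length(cuts) < 2L) next
      cuts <- sort(cuts)
      thr <- (cuts[-1L] + cuts[-length(cuts)]) / 2
      if (length(thr) > 32L)
        thr <- quantile(xs, probs = seq(0.03, 0.97, length.out = 32L),
                        names = FALSE, type = 7)
      for (t in thr) {
        left <- xs <= t
        nl <- sum(left); nr <- n - nl
        if (nl == 0L || nr == 0L) next
        gini <- function(v) { p <- tabulate(as.integer(v), length(lv)) / length(v)
                              1 - sum(p^2) }
        g <- (nl * gini(yi[left]) + nr * gini(yi[!left])) / n
        if (g < best_gini - 1e-12) { best_gini <- g; best <- list(j = j, t = t) }
      }
    }
    if (is.null(best)) return(leaf)
    left <- x[idx, best$j] <= best$t
    list(leaf = FALSE, j = best$j, t = best$t,
         l = grow(idx[left], depth + 1L), r = grow(idx[!left], depth + 1L))
  }
  list(tree = grow(seq_len(nrow(x)), 0L), levels = lv)
}

cart_predict <- function(x_train, y_train, x_test, min_split, max_depth) {
  fit <- cart_fit(x_train, y_train, min_split, max_depth)
  classify <- function(node, row) {
    while (!node$leaf) node <- if (row[node$j] <= node$t) node$l else node$r
    node$class
  }
  pred <- vapply(seq_len(nrow(x_test)), function(i)
    classify(fit$tree, x_test[i, ]), "")
  factor(pred, levels = fit$levels)
}
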