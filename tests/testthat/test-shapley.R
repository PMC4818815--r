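test_that("build_pairwise_cache entries equal direct estimator calls", {
  withr::with_seed(31, {
    n <- 100
    codes <- cbind(sample(0:4, n, TRUE), sample(0:4, n, TRUE),
                   sample(0:2, n, TRUE), sample(0:4, n, TRUE),
                   sample(0:1, n, TRUE))
    cls <- sample(0:1, n, TRUE)
  })
  cache <- build_pairwise_cache(codes, as_discretized(cls))
  dcls <- as_discretized(cls)
  for (j in 1:5) {
    expect_equal(cache$qmi_class[j],
                 mutual_information(as_discretized(codes[, j]), dcls),
                 tolerance = 1e-12)
    for (i in setdiff(1:5, j)) {
      expect_equal(cache$cmi_given[i, j],
                   conditional_mutual_information(as_discretized(codes[, j]),
                                                  dcls,
                                                  as_discretized(codes[, i])),
                   tolerance = 1e-12)
    }
  }
  # Fisher utility scales the qmi vector
  u <- c(2, 0.5, 1, 3, 0)
  cache_u <- build_pairwise_cache(codes, dcls, u)
  expect_equal(cache_u$qmi_class, cache$mi_class * u, tolerance = 1e-14)
  # duplicate features: conditioning on the twin leaves nothing
  dup <- cbind(codes[, 1], codes[, 1], codes[, 2])
  cache_d <- build_pairwise_cache(dup, dcls)
  expect_equal(cache_d$cmi_given[1, 2], 0)
  expect_equal(cache_d$cmi_given[2, 1], 0)
})

test_that("interdependence index: XOR is 1, duplicate and constant are 0", {
  xo <- xor_codes(4L)
  cache <- build_pairwise_cache(xo$codes, as_discretized(xo$class))
  expect_equal(cache$cmi_given[1, 2], 1.0)   # CMI(f2; class | f1) = 1 bit
  expect_equal(cache$qmi_class[2], 0.0)      # QMI(f2; class) = 0
  expect_equal(interdependence_index(1, 2, cache), 1L)
  dup <- cbind(xo$codes[, 1], xo$codes[, 1])
  cache_dup <- build_pairwise_cache(dup, as_discretized(xo$class))
  expect_equal(interdependence_index(1, 2, cache_dup), 0L)
  # constant f_j: CMI = QMI = 0, strict > fails
  cc <- build_pairwise_cache(cbind(xo$codes[, 1], 0L),
                             as_discretized(xo$class))
  expect_equal(interdependence_index(1, 2, cc), 0L)
  expect_error(interdependence_index(2, 2, cache), class = "shapleyFS_bad_index")
})

test_that("set_relevance and relevance_change are the stated means", {
  cache <- fake_cache(qmi = c(0.2, 0.4, 0.6, 0.1),
                      cmi = matrix(0.3, 4, 4))
  expect_equal(set_relevance(2, cache), 0.4)
  expect_equal(set_relevance(1:3, cache), 0.4)
  expect_equal(set_relevance(c(1, 1, 1), fake_cache(rep(0, 3), matrix(0, 3, 3))), 0)
  expect_error(set_relevance(integer(0), cache), class = "shapleyFS_empty_set")
  # per-term values 0.3 - qmi
  expect_equal(relevance_change(c(1, 2), 4, cache),
               mean(c(0.3 - 0.2, 0.3 - 0.4)))
  expect_error(relevance_change(c(1, 2), 2, cache), class = "shapleyFS_bad_index")
  # XOR pair: 1 - 0 = 1
  xo <- xor_codes(4L)
  cx <- build_pairwise_cache(xo$codes, as_discretized(xo$class))
  expect_equal(relevance_change(2, 1, cx), 1.0)
})

test_that("coalition payoff implements both conditions with stated strictness", {
  # negative relevance change vetoes regardless of psi
  cache <- fake_cache(qmi = c(0.9, 0.9, 0), cmi = matrix(1, 3, 3))
  cache$cmi_given[3, 1:2] <- 0   # d = -0.9 for both members
  expect_equal(coalition_payoff(c(1, 2), 3, cache), 0L)
  # |K| = 2, psi sum = 1 meets the >= |K|/2 boundary
  cache2 <- fake_cache(qmi = c(0.5, 0.5, 0), cmi = matrix(0, 3, 3))
  cache2$cmi_given[3, 1] <- 0.9   # psi(3,1) = 1, d = +0.4
  cache2$cmi_given[3, 2] <- 0.5   # psi(3,2) = 0 (tie), d = 0
  expect_equal(coalition_payoff(c(1, 2), 3, cache2), 1L)
  # both members duplicates of f_i: d = 0 passes but psi sum 0 < |K|/2 = 1
  cache3 <- fake_cache(qmi = c(0, 0, 0), cmi = matrix(0, 3, 3))
  expect_equal(coalition_payoff(c(1, 2), 3, cache3), 0L)
})

test_that("shapley equals exhaustive enumeration for n <= 10, k = 1..3", {
  withr::with_seed(404, {
    for (rep in 1:15) {
      n <- sample(4:10, 1)
      cache <- random_cache(n)
      for (k in 1:3) {
        if (k >= n) next
        w <- shapleyFS:::compute_all_weights_from_cache(cache, k)
        expect_equal(w$phi, oracle_shapley(cache, k), tolerance = 1e-13)
        expect_true(all(w$phi >= 0 & w$phi <= 1 / n + 1e-15))
      }
    }
  })
})

test_that("analytic spot check: all-qualifying feature at n = 4, k = 2", {
  # every pair interdependent and relevance-raising -> 3 coalitions,
  # each with weight 2! 1! / 4! = 1/12, phi = 3/12 = 0.25
  cache <- fake_cache(qmi = rep(0.1, 4), cmi = matrix(0.5, 4, 4))
  w <- shapleyFS:::compute_all_weights_from_cache(cache, 2)
  expect_equal(w$phi, rep(0.25, 4))
  expect_equal(shapley_value(1, cache, 2), 0.25)
  # zero-payoff feature -> 0
  cache$cmi_given[2, ] <- 0   # d negative for everything feature 2 joins
  w2 <- shapleyFS:::compute_all_weights_from_cache(cache, 2)
  expect_equal(w2$phi[2], 0)
})

test_that("compute_all_weights: permutation equivariance and planted XOR", {
  withr::with_seed(12, {
    n <- 60
    codes <- cbind(sample(0:2, n, TRUE), sample(0:2, n, TRUE),
                   sample(0:2, n, TRUE), sample(0:2, n, TRUE),
                   sample(0:2, n, TRUE))
    cls <- sample(0:1, n, TRUE)
  })
  w <- compute_all_weights(codes, as_discretized(cls))
  perm <- c(3L, 1L, 5L, 2L, 4L)
  w_perm <- compute_all_weights(codes[, perm], as_discretized(cls))
  expect_equal(w_perm$phi, w$phi[perm], tolerance = 1e-13)
  # all-duplicate features: nothing is interdependent, phi = 0
  dupes <- matrix(rep(codes[, 1], 4), ncol = 4)
  w_dup <- compute_all_weights(dupes, as_discretized(cls))
  expect_equal(w_dup$phi, rep(0, 4))
  # planted XOR structure outranks unrelated features. With random finite
  # samples the plug-in CMI bias makes psi fire spuriously for everything
  # (the binary payoff ignores magnitudes), so the discriminating construction
  # is a full factorial: every feature pair exactly independent, class =
  # xor(f1, f2) exactly. Seeds randomize row and column order.
  grid <- as.matrix(expand.grid(rep(list(0:1), 6)))
  cls_x <- bitwXor(grid[, 1], grid[, 2])
  hits <- vapply(1:10, function(s) {
    withr::with_seed(7000 + s, {
      rows <- sample.int(nrow(grid))
      cols <- sample.int(6)
      ww <- compute_all_weights(grid[rows, cols],
                                as_discretized(cls_x[rows]))
      xor_pos <- match(1:2, cols)
      min(ww$phi[xor_pos]) > max(ww$phi[-xor_pos])
    })
  }, TRUE)
  expect_true(all(hits))
})

test_that("coalition size is validated and k > 3 warns", {
  cache <- random_cache(6)
  expect_error(shapleyFS:::compute_all_weights_from_cache(cache, 0),
               class = "shapleyFS_bad_coalition")
  expect_error(shapleyFS:::compute_all_weights_from_cache(cache, 6),
               class = "shapleyFS_bad_coalition")
  expect_warning(shapleyFS:::compute_all_weights_from_cache(cache, 4),
                 "expensive")
})
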