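test_that("discretize: bin placement, ties, degenerate inputs", {
  # median split of 1..10
  expect_equal(discretize(1:10, 2)$codes, rep(0:1, each = 5))
  # constant collapses to one occupied bin
  d <- discretize(rep(3.7, 8), 5)
  expect_true(all(d$codes == 0L))
  expect_equal(length(unique(d$codes)), 1L)
  # equal-frequency bin counts within +/-1 of n/B
  x <- withr::with_seed(1, rnorm(1000))
  cnt <- tabulate(discretize(x, 5)$codes + 1L, 5)
  expect_true(all(abs(cnt - 200) <= 1))
  # uneven n: sizes differ by at most one
  cnt2 <- tabulate(discretize(withr::with_seed(2, rnorm(103)), 5)$codes + 1L, 5)
  expect_lte(diff(range(cnt2)), 1L)
  # equal width
  ew <- discretize(c(0, 0.1, 0.2, 0.9, 1), 2, "equal_width")
  expect_equal(ew$codes, c(0L, 0L, 0L, 1L, 1L))
  expect_error(discretize(1:5, 0), class = "shapleyFS_bad_bins")
  expect_error(discretize(c(1, NA), 2), class = "shapleyFS_nonfinite")
})

test_that("entropy matches hand values and bounds", {
  expect_equal(entropy(as_discretized(c(0, 1, 0, 1))), 1.0)
  expect_equal(entropy(as_discretized(rep(1, 6))), 0.0)
  expect_equal(entropy(as_discretized(c(0, 0, 0, 1))),
               -(0.75 * log2(0.75) + 0.25 * log2(0.25)))
})

test_that("MI: identity, independence, and a cell-by-cell oracle", {
  b <- as_discretized(c(0, 1, 0, 1))
  expect_equal(mutual_information(b, b), 1.0)
  ind <- list(x = as_discretized(c(0, 0, 1, 1)), y = as_discretized(c(0, 1, 0, 1)))
  expect_equal(mutual_information(ind$x, ind$y), 0.0)
  # joint counts {(0,0):4,(0,1):1,(1,0):1,(1,1):4}
  x <- as_discretized(c(rep(0, 5), rep(1, 5)))
  y <- as_discretized(c(rep(0, 4), 1, 0, rep(1, 4)))
  expect_equal(mutual_information(x, y), oracle_mi(x$codes, y$codes),
               tolerance = 1e-14)
  expect_error(mutual_information(as_discretized(0:1), as_discretized(0:2)),
               class = "shapleyFS_length_mismatch")
})

test_that("QMI is utility-scaled MI", {
  x <- as_discretized(c(rep(0, 5), rep(1, 5)))
  y <- as_discretized(c(rep(0, 4), 1, 0, rep(1, 4)))
  mi <- mutual_information(x, y)
  expect_identical(qualitative_mutual_information(x, y, utility_spec("constant_one")),
                   mi)
  expect_equal(qualitative_mutual_information(x, y, utility_spec("fisher", 2.5)),
               2.5 * mi)
  expect_equal(qualitative_mutual_information(x, y, utility_spec("fisher", 0)), 0)
  expect_error(utility_spec("fisher", -1), class = "shapleyFS_bad_utility")
})

test_that("CMI: vacuous conditioning, XOR, conditional independence", {
  x <- as_discretized(c(0, 0, 1, 1, 0, 1))
  y <- as_discretized(c(0, 1, 0, 1, 1, 0))
  z_const <- as_discretized(rep(0, 6))
  expect_equal(conditional_mutual_information(x, y, z_const),
               mutual_information(x, y), tolerance = 1e-14)
  # XOR: z = x xor y with balanced x, y -> CMI(x;y|z) = 1 bit, MI(x;y) = 0
  xo <- xor_codes(4L)
  xd <- as_discretized(xo$codes[, 1]); yd <- as_discretized(xo$codes[, 2])
  zd <- as_discretized(xo$class)
  expect_equal(mutual_information(xd, yd), 0)
  expect_equal(conditional_mutual_information(xd, yd, zd), 1.0)
  # conditional independence given z: sample x and y independently per stratum
  big <- withr::with_seed(99, {
    z <- sample(0:2, 1e4, replace = TRUE)
    x <- rbinom(1e4, 1, c(0.2, 0.5, 0.8)[z + 1])
    y <- rbinom(1e4, 1, c(0.7, 0.4, 0.1)[z + 1])
    conditional_mutual_information(as_discretized(x), as_discretized(y),
                                   as_discretized(z))
  })
  expect_lt(big, 0.002)  # estimator noise only at n = 1e4
})

test_that("SU: perfect predictor, independence, 2x2 oracle, bounds", {
  cls <- as_discretized(c(0, 1, 0, 1))
  expect_equal(symmetric_uncertainty(cls, cls), 1.0)
  ind <- as_discretized(c(0, 0, 1, 1))
  expect_equal(symmetric_uncertainty(ind, cls), 0.0)
  f <- as_discretized(c(0, 1, 0, 0))   # agrees on 3 of 4
  expect_equal(symmetric_uncertainty(f, cls), oracle_su(f$codes, cls$codes),
               tolerance = 1e-14)
  expect_equal(symmetric_uncertainty(as_discretized(rep(0, 4)), cls), 0)
  expect_error(symmetric_uncertainty(cls, as_discretized(rep(0, 4))),
               class = "shapleyFS_constant_class")
})

test_that("property: estimators track the brute-force oracle on random input", {
  withr::with_seed(2024, {
    for (rep in 1:40) {
      n <- sample(30:300, 1)
      sx <- sample(2:5, 1); sy <- sample(2:5, 1); sz <- sample(2:5, 1)
      x <- sample(0:(sx - 1), n, replace = TRUE)
      y <- sample(0:(sy - 1), n, replace = TRUE)
      z <- sample(0:(sz - 1), n, replace = TRUE)
      dx <- as_discretized(x); dy <- as_discretized(y); dz <- as_discretized(z)
      expect_lt(abs(entropy(dx) - oracle_entropy(x)), 1e-12)
      mi <- mutual_information(dx, dy)
      expect_lt(abs(mi - oracle_mi(x, y)), 1e-12)
      expect_lte(mi, min(entropy(dx), entropy(dy)) + 1e-12)
      expect_lt(abs(mutual_information(dy, dx) - mi), 1e-14)  # symmetry
      cmi <- conditional_mutual_information(dx, dy, dz)
      expect_lt(abs(cmi - oracle_cmi(x, y, z)), 1e-12)
      expect_gte(cmi, 0)
      expect_lt(abs(conditional_mutual_information(dy, dx, dz) - cmi), 1e-12)
    }
  })
})

test_that("property: chain rule MI(x;y) + CMI(x;z|y) = MI(x;(y,z))", {
  withr::with_seed(7, {
    for (rep in 1:20) {
      n <- 200
      x <- sample(0:2, n, replace = TRUE)
      y <- sample(0:1, n, replace = TRUE)
      z <- (x + y + sample(0:1, n, replace = TRUE)) %% 3
      yz <- y * 3 + z   # joint coding
      lhs <- mutual_information(as_discretized(x), as_discretized(y)) +
        conditional_mutual_information(as_discretized(x), as_discretized(z),
                                       as_discretized(y))
      rhs <- mutual_information(as_discretized(x), as_discretized(yz))
      expect_equal(lhs, rhs, tolerance = 1e-10)
    }
  })
})
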