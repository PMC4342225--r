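test_that("equal-frequency discretization honours its occupancy contract", {
  expect_equal(as.integer(discretize_equal_frequency(c(1, 2, 3, 4), 2)),
               c(0L, 0L, 1L, 1L))
  expect_equal(unique(as.integer(discretize_equal_frequency(rep(3.3, 7), 5))), 0L)
  withr::with_seed(1, z <- rnorm(1000))
  codes <- discretize_equal_frequency(z, 10)
  expect_equal(unname(table(codes)), rep(100L, 10), ignore_attr = TRUE)
  # integer-coded input with few distinct values keeps its grouping
  v <- c(5, 7, 5, 9, 7)
  expect_equal(as.integer(discretize_equal_frequency(v, 10)),
               c(0L, 1L, 0L, 2L, 1L))
  # ties spanning a bin boundary collapse into one bin
  tied <- c(1, 2, 2, 2, 3, 4)
  ct <- as.integer(discretize_equal_frequency(tied, 3))
  expect_length(unique(ct[tied == 2]), 1)
})

test_that("mutual information matches exact hand cases", {
  expect_equal(mutual_information(c(0, 1, 0, 1), c("a", "b", "a", "b")), 1.0)
  expect_equal(mutual_information(rep(0, 8), rep(c("a", "b"), 4)), 0.0)
  expect_equal(mutual_information(c(0, 0, 1, 1), c(0, 1, 0, 1)), 0.0)
  expect_error(mutual_information(1:3, 1:4), "equal length")
})

test_that("MI and CMI agree with brute-force contingency oracles", {
  withr::with_seed(99, {
    for (i in 1:50) {
      n <- sample(8:64, 1)
      x <- sample(0:sample(1:3, 1), n, replace = TRUE)
      y <- sample(0:sample(1:3, 1), n, replace = TRUE)
      z <- sample(0:sample(1:3, 1), n, replace = TRUE)
      expect_equal(mutual_information(x, y), mi_oracle(x, y), tolerance = 1e-12)
      expect_equal(conditional_mutual_information(x, y, z),
                   cmi_oracle(x, y, z), tolerance = 1e-12)
    }
  })
})

test_that("CMI special cases and chain rule hold", {
  x <- c(0, 1, 0, 1, 1, 0, 1, 0)
  y <- c(1, 0, 1, 0, 0, 1, 0, 1)
  z_const <- rep(0, 8)
  expect_equal(conditional_mutual_information(x, y, z_const),
               mutual_information(x, y))
  expect_equal(conditional_mutual_information(x, y, x), 0.0)

  # exact XOR triple: y = x XOR z on the full factorial
  g <- expand.grid(x = 0:1, z = 0:1)
  g <- g[rep(1:4, 4), ]
  yy <- as.integer(xor(g$x == 1, g$z == 1))
  expect_equal(mutual_information(g$x, yy), 0.0)
  expect_equal(conditional_mutual_information(g$x, yy, g$z), 1.0)

  # chain identity CMI(x;y|z) = MI((x,z);y) - MI(z;y), plug-in exact
  withr::with_seed(5, {
    for (i in 1:20) {
      n <- 40
      x <- sample(0:2, n, TRUE); y <- sample(0:1, n, TRUE); z <- sample(0:2, n, TRUE)
      lhs <- conditional_mutual_information(x, y, z)
      rhs <- mutual_information(paste(x, z), y) - mutual_information(z, y)
      expect_equal(lhs, rhs, tolerance = 1e-12)
    }
  })
})

test_that("symmetry and sample-order invariance", {
  withr::with_seed(21, {
    x <- sample(0:3, 60, TRUE)
    y <- sample(0:2, 60, TRUE)
    expect_equal(mutual_information(x, y), mutual_information(y, x))
  })
  sim <- make_informative_dataset(n_samples = 120, n_informative = 3,
                                  n_noise = 5, seed = 4)
  perm <- withr::with_seed(2, sample(120))
  r1 <- rank_features(sim$data, "jmi", n_select = 4)
  r2 <- rank_features(sim$data[perm, ], "jmi", n_select = 4)
  expect_equal(r1$feature, r2$feature)
  expect_equal(r1$score, r2$score, tolerance = 1e-12)
})

test_that("greedy criteria penalize an exact duplicate of a selected feature", {
  sim <- make_informative_dataset(n_samples = 300, n_informative = 2,
                                  n_redundant = 0, n_noise = 3,
                                  class_sep = 4, seed = 6)
  d <- sim$data
  d$f1 <- d$f2   # feature 1 duplicates feature 2 exactly
  for (crit in c("mrmr", "jmi", "cmim", "icap")) {
    r <- rank_features(d, crit, n_select = 2)
    expect_equal(sum(r$feature[1:2] %in% 1:2), 1,
                 label = sprintf("%s keeps exactly one of the duplicate pair", crit))
  }
})

test_that("CMIM finds the XOR partner right after the first informative pick", {
  d <- make_xor_factorial(n_noise_bits = 3)   # exact zero univariate MIs
  r <- rank_features(d, "cmim", n_select = 2, n_bins = 2)
  # all univariate MIs are exactly 0, so the tie-break picks feature 1 first;
  # conditioning on it makes its XOR partner worth a full bit
  expect_equal(r$feature[1], 1L)
  expect_equal(r$feature[2], 2L)
  expect_equal(r$score[2], 1.0)
})

test_that("rank_features over all features yields a permutation", {
  sim <- make_informative_dataset(n_samples = 80, n_informative = 2,
                                  n_noise = 4, seed = 3)
  for (crit in c("mrmr", "jmi", "cmim", "icap")) {
    r <- rank_features(sim$data, crit)
    expect_setequal(r$feature, 1:6)
  }
})

test_that("correlation ranking matches a direct oracle and its conventions", {
  d <- make_separable_data(n = 40, n_features = 2, sep = 0, seed = 13)
  d$f1 <- ifelse(d$class == "pos", 1, -1)     # perfect encoding
  d$f2 <- 5                                    # zero variance
  r <- correlation_ranking(d)
  expect_equal(r$feature[1], 1L)
  expect_equal(r$score[1], 1.0)
  expect_equal(r$score[r$feature == 2], 0.0)

  withr::with_seed(31, {
    x <- matrix(rnorm(500), 50, 10)
    dd <- tibble::as_tibble(as.data.frame(x))
    dd$class <- sample(c("a", "b"), 50, TRUE)
    rr <- correlation_ranking(dd)
    enc <- as.numeric(dd$class == "b")
    oracle <- abs(apply(x, 2, cor, y = enc))
    expect_equal(rr$score, oracle[rr$feature], tolerance = 1e-12)
    expect_equal(rr$feature, order(-oracle, 1:10))
  })
})

test_that("top-fraction selection applies the ceiling-with-floor-one rule", {
  sim <- make_informative_dataset(n_samples = 60, n_informative = 2,
                                  n_noise = 5, seed = 2)
  r <- rank_features(sim$data, "mrmr")
  expect_length(select_top_fraction(r, 0.1), 1)       # ceil(0.7) -> 1
  expect_length(select_top_fraction(r, 0.3), 3)       # ceil(2.1) -> 3
  expect_length(select_top_fraction(r, 1.0), 7)
  expect_equal(select_top_fraction(r, 0.3), r$feature[1:3])
  expect_error(select_top_fraction(r, 0), "fraction")
})
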