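test_that("the sample-correlation likelihood is a proper density", {
  for (n in c(5, 20)) {
    for (rho in c(0, 0.5, -0.7)) {
      I <- integrate(function(r) {
        vapply(r, function(ri) sees:::.pearson_r_density(ri, rho, n), 0)
      }, -1, 1, rel.tol = 1e-9)$value
      expect_equal(I, 1, tolerance = 1e-6)
    }
  }
})

test_that("pearson Bayes factors match a fine-grid quadrature oracle", {
  set.seed(50)
  n <- 50
  x <- rnorm(n)
  y <- 0.6 * x + sqrt(1 - 0.36) * rnorm(n)
  res <- pearson_bf(x, y)
  oracle <- pearson_grid_oracle(x, y)
  expect_equal(res$bf10, oracle$bf10, tolerance = 0.01)
  expect_equal(res$bf_plus0, oracle$bf_plus0, tolerance = 0.01)
  expect_equal(res$bf_minus0, oracle$bf_minus0, tolerance = 0.01)
})

test_that("directional Bayes factors are reciprocal and sign-symmetric", {
  set.seed(8)
  x <- rnorm(25)
  y <- 0.3 * x + rnorm(25)
  for (res in list(pearson_bf(x, y), pearson_bf(x, y, kappa = 0.5),
                   spearman_bf(x, y, draws = 1500, warmup = 500, seed = 2))) {
    expect_equal(res$bf_plus0 * res$bf_0plus, 1, tolerance = 1e-9)
    expect_equal(res$bf_minus0 * res$bf_0minus, 1, tolerance = 1e-9)
    expect_true(abs(res$estimate) <= 1)
    expect_true(all(res$ci95 >= -1 & res$ci95 <= 1))
    expect_lte(res$ci95[1], res$estimate)
    expect_gte(res$estimate, res$ci95[1])
  }
  # flipping the sign of one variable swaps the tested directions
  a <- pearson_bf(x, y)
  b <- pearson_bf(x, -y)
  expect_equal(a$bf_plus0, b$bf_minus0, tolerance = 1e-6)
  expect_equal(a$estimate, -b$estimate, tolerance = 1e-6)
})

test_that("the two-sided BF is the prior-weighted mix of the one-sided BFs", {
  set.seed(13)
  x <- rnorm(30)
  y <- rnorm(30)
  res <- pearson_bf(x, y)
  expect_equal(res$bf10, 0.5 * res$bf_plus0 + 0.5 * res$bf_minus0,
               tolerance = 1e-6)
})

test_that("degenerate correlation inputs raise informative errors", {
  expect_error(pearson_bf(rep(1, 10), rnorm(10)), "degenerate")
  expect_error(pearson_bf(rnorm(2), rnorm(2)), "insufficient")
  expect_error(pearson_bf(rnorm(5), rnorm(4)), "equal length")
  expect_error(spearman_bf(rep(2, 8), rnorm(8)), "degenerate")
})

test_that("rank-based results are invariant under monotone transforms", {
  set.seed(91)
  x <- rnorm(30)
  y <- 0.4 * x + rnorm(30)
  a <- spearman_bf(x, y, draws = 1200, warmup = 400, seed = 7)
  b <- spearman_bf(exp(3 * x), y, draws = 1200, warmup = 400, seed = 7)
  expect_identical(a$estimate, b$estimate)
  expect_identical(a$bf_plus0, b$bf_plus0)
})

test_that("evidence for a true positive correlation accumulates with n", {
  set.seed(60)
  bf <- vapply(c(20, 80), function(n) {
    x <- rnorm(n)
    y <- 0.7 * x + sqrt(1 - 0.49) * rnorm(n)
    spearman_bf(x, y, draws = 2000, warmup = 500, seed = n)$bf_plus0
  }, 0)
  expect_gt(bf[1], 1)
  expect_gt(bf[2], bf[1])
  expect_gt(bf[2], 100)
})

test_that("spearman and pearson agree on clean bivariate-normal data", {
  set.seed(23)
  n <- 120
  x <- rnorm(n)
  y <- 0.5 * x + sqrt(0.75) * rnorm(n)
  ps <- pearson_bf(x, y)
  sp <- spearman_bf(x, y, draws = 2500, warmup = 500, seed = 3)
  expect_equal(sp$estimate, 6 / pi * asin(ps$estimate / 2), tolerance = 0.12)
})
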