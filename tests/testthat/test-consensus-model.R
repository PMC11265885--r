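test_that("category probabilities partition the real line", {
  set.seed(3)
  for (i in 1:20) {
    gamma <- sort(rnorm(3, sd = 1.5))
    if (any(diff(gamma) == 0)) next
    p <- category_probability(rnorm(1), exp(rnorm(1, 0, 0.5)), rnorm(1),
                              gamma, 1:4)
    expect_true(all(p >= 0))
    expect_equal(sum(p), 1, tolerance = 1e-12)
  }
})

test_that("category probability matches the normal-CDF closed form", {
  # P(X = 1) at T = 0, beta = 0, lambda = 1, gamma = (-1, 0, 1) is Phi(-1)
  expect_equal(category_probability(0, 1, 0, c(-1, 0, 1), 1),
               pnorm(-1), tolerance = 1e-12)
  expect_equal(round(category_probability(0, 1, 0, c(-1, 0, 1), 1), 6),
               0.158655)
  # symmetry of the extreme categories under symmetric thresholds
  p <- category_probability(0, 1.3, 0, c(-0.8, 0, 0.8), 1:4)
  expect_equal(p[1], p[4], tolerance = 1e-12)
  expect_equal(p[2], p[3], tolerance = 1e-12)
})

test_that("category probability agrees with a Monte-Carlo binning oracle", {
  n <- 1e5
  cases <- list(c(T = 0.4, lam = 1.2, beta = -0.3),
                c(T = -1.1, lam = 0.7, beta = 0.5),
                c(T = 0, lam = 1, beta = 0))
  gamma <- c(-1.2, 0, 1.2)
  for (k in seq_along(cases)) {
    cs <- cases[[k]]
    p_hat <- mc_category_oracle(cs["T"], cs["lam"], cs["beta"], gamma,
                                n = n, seed = 100 + k)
    p <- category_probability(cs["T"], cs["lam"], cs["beta"], gamma, 1:4)
    se <- sqrt(p * (1 - p) / n)
    expect_true(all(abs(p_hat - p) <= 3 * se + 1e-12),
                info = paste("case", k))
  }
})

test_that("probability is invariant along the model's translation ridges", {
  # the likelihood sees parameters only through gamma_c + beta - T, so a
  # common shift of (thresholds, location) or of (scepticism, location)
  # changes nothing; these are the directions the identification
  # constraints (mean-zero thresholds and scepticism) pin down
  gamma <- c(-1, 0.2, 1.4)
  p0 <- category_probability(0.3, 0.9, -0.2, gamma, 1:4)
  for (d in c(-2, 0.7, 5)) {
    expect_equal(category_probability(0.3 + d, 0.9, -0.2, gamma + d, 1:4),
                 p0, tolerance = 1e-12)
    expect_equal(category_probability(0.3 + d, 0.9, -0.2 + d, gamma, 1:4),
                 p0, tolerance = 1e-12)
  }
  # the common scale of (location, thresholds, scepticism, dispersion) is
  # equally invisible to the likelihood
  for (s in c(0.5, 3)) {
    expect_equal(
      category_probability(0.3 * s, 0.9 * s, -0.2 * s, gamma * s, 1:4),
      p0, tolerance = 1e-12)
  }
})

test_that("more scepticism strictly lowers the top-category probability", {
  betas <- seq(-1, 1, by = 0.25)
  pC <- vapply(betas,
               function(b) category_probability(0.5, 1, b, c(-1, 0, 1), 4), 0)
  expect_true(all(diff(pC) < 0))
})

test_that("invalid likelihood parameters are rejected", {
  expect_error(category_probability(0, -1, 0, c(-1, 0, 1), 1), "lam")
  expect_error(category_probability(0, 1, 0, c(0, -1, 1), 1), "increasing")
  expect_error(category_probability(0, 1, 0, c(-1, 0, 1), 5), "range")
})

test_that("fit rejects unusable inputs", {
  inst <- synthetic_instrument(3)
  v <- matrix(sample(1:4, 30, replace = TRUE), 10, 3,
              dimnames = list(NULL, c("item_1", "item_2", "item_3")))
  tab <- as_sees_responses(v)
  expect_error(
    fit_consensus(tab, inst, "methodological_appropriateness", tiny_config()),
    "no items")
  tab4 <- as_sees_responses(v[1:4, ])
  expect_error(fit_consensus(tab4, inst, "subjective_evidence", tiny_config()),
               ">= 5 teams")
  tab_unrev <- tab
  tab_unrev$reversed <- FALSE
  expect_error(
    fit_consensus(tab_unrev, inst, "subjective_evidence", tiny_config()),
    "reverse coding")
})

test_that("fits are draw-identical under a fixed seed", {
  inst <- synthetic_instrument(3)
  cfg <- simulation_config(K = 12, items = 3, seed = 5)
  tab <- simulate_responses(draw_truth(cfg), cfg)
  f1 <- suppressWarnings(fit_consensus(tab, inst, "subjective_evidence",
                                       tiny_config(seed = 9)))
  f2 <- suppressWarnings(fit_consensus(tab, inst, "subjective_evidence",
                                       tiny_config(seed = 9)))
  expect_identical(f1$draws, f2$draws)
})

test_that("unanimous top-category responses push consensus above the last threshold", {
  inst <- synthetic_instrument(3)
  v <- matrix(4L, 12, 3, dimnames = list(NULL, paste0("item_", 1:3)))
  tab <- as_sees_responses(v)
  fit <- suppressWarnings(fit_consensus(tab, inst, "subjective_evidence",
                                        tiny_config(seed = 2)))
  g_top <- median(fit$draws$gamma[, 3])
  med <- apply(fit$draws$T, 2, median)
  expect_true(all(med > g_top))
})

test_that("summary quantities re-derive from the raw draws", {
  inst <- synthetic_instrument(4)
  cfg <- simulation_config(K = 20, items = 4, seed = 8)
  tab <- simulate_responses(draw_truth(cfg), cfg)
  fit <- suppressWarnings(fit_consensus(tab, inst, "subjective_evidence",
                                        tiny_config(seed = 4)))
  s <- summarize_consensus(fit, inst)
  # overall consensus is the median/CI of the per-draw item mean
  om <- rowMeans(fit$draws$T)
  expect_equal(unname(s$overall["median"]), median(om))
  expect_equal(unname(s$overall["lower"]),
               unname(quantile(om, 0.025)))
  expect_equal(s$sd_across_items,
               sd(apply(fit$draws$T, 2, median)))
  expect_equal(s$thresholds, apply(fit$draws$gamma, 2, median),
               ignore_attr = TRUE)
  # identification constraints hold draw-wise after recentering
  expect_true(all(abs(rowMeans(fit$draws$gamma)) < 1e-12))
  expect_true(all(abs(rowMeans(fit$draws$beta)) < 1e-12))
  # ordered thresholds and positive dispersions in every draw
  expect_true(all(fit$draws$gamma[, 1] < fit$draws$gamma[, 2]))
  expect_true(all(fit$draws$gamma[, 2] < fit$draws$gamma[, 3]))
  expect_true(all(fit$draws$lam > 0))
  # intervals bracket their medians
  expect_true(all(s$items$lower <= s$items$median))
  expect_true(all(s$items$median <= s$items$upper))
})

test_that("a single-item summary reports zero spread across items", {
  inst <- synthetic_instrument(4)
  cfg <- simulation_config(K = 20, items = 4, seed = 8)
  tab <- simulate_responses(draw_truth(cfg), cfg)
  fit <- suppressWarnings(fit_consensus(tab, inst, "subjective_evidence",
                                        tiny_config(seed = 4)))
  fit1 <- fit
  fit1$draws$T <- fit$draws$T[, 1, drop = FALSE]
  fit1$draws$lam <- fit$draws$lam[, 1, drop = FALSE]
  fit1$item_ids <- fit$item_ids[1]
  s1 <- summarize_consensus(fit1, inst)
  expect_equal(s1$sd_across_items, 0)
})

test_that("consensus medians map to labels with ties going up", {
  inst <- synthetic_instrument(3)
  summ <- structure(list(
    items = data.frame(item_id = paste0("item_", 1:3),
                       median = c(-2, 0.5, 1.2), lower = 0, upper = 0,
                       stringsAsFactors = FALSE),
    thresholds = c(-1.2, 0.5, 1.2),
    subscale = "subjective_evidence", C = 4L), class = "sees_summary")
  labs <- label_consensus(summ, inst)
  expect_equal(labs[1], "cat_1") # below the first threshold
  expect_equal(labs[2], "cat_3") # exactly on a threshold: higher category
  expect_equal(labs[3], "cat_4")
})
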