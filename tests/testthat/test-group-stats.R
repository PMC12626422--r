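test_that("Pearson test reproduces the closed-form t and guards inputs", {
  x <- c(1, 2, 3, 4, 5)
  res <- pearson_test(x, 2 * x + 1)
  expect_equal(res$estimate, 1, tolerance = 1e-12)
  expect_lt(res$p_raw, 1e-10)
  expect_equal(res$df, 3)

  set.seed(51)
  a <- rnorm(20); b <- rnorm(20)
  res2 <- pearson_test(a, b)
  r <- bf_pearson(a, b)
  t_hand <- r * sqrt(18 / (1 - r^2))
  expect_equal(res2$statistic, t_hand, tolerance = 1e-10)
  expect_equal(res2$p_raw, 2 * pt(abs(t_hand), 18, lower.tail = FALSE),
               tolerance = 1e-12)

  expect_error(pearson_test(1:2, 2:3), "n >= 3")
  expect_error(pearson_test(rep(1, 5), rnorm(5)), "zero variance")
})

test_that("partial correlation equals the one-covariate closed form", {
  set.seed(52)
  for (i in 1:20) {
    n <- 30
    z <- rnorm(n)
    x <- 0.5 * z + rnorm(n)
    y <- -0.3 * z + rnorm(n)
    res <- partial_correlation(x, y, z)
    r_xy <- cor(x, y); r_xz <- cor(x, z); r_yz <- cor(y, z)
    closed <- (r_xy - r_xz * r_yz) / sqrt((1 - r_xz^2) * (1 - r_yz^2))
    expect_lt(abs(res$estimate - closed), 1e-12)
    expect_equal(res$df, n - 3)
  }

  # the textbook example: r_xy = 0.6, r_xz = r_yz = 0.5 -> 0.35 / 0.75
  closed_toy <- (0.6 - 0.5 * 0.5) / sqrt((1 - 0.25) * (1 - 0.25))
  expect_equal(closed_toy, 0.35 / 0.75, tolerance = 1e-12)

  # covariate orthogonal to both variables leaves r unchanged
  x <- c(1, 2, 3, 5, 4, 7, 6, 9)
  y <- c(2, 1, 4, 4, 6, 5, 8, 7)
  z <- resid(lm(rnorm(8) ~ x + y))
  expect_equal(partial_correlation(x, y, z)$estimate, cor(x, y),
               tolerance = 1e-10)

  expect_error(partial_correlation(x, y, x), "rank deficient|residual")
  expect_error(partial_correlation(1:4, 1:4, cbind(1:4, 1:4)),
               "rank deficient|n > k")
})

test_that("BH adjustment matches the hand computation and is stable", {
  expect_equal(fdr_bh(c(0.01, 0.02, 0.03)), rep(0.03, 3))
  expect_equal(fdr_bh(0.2), 0.2)
  expect_equal(fdr_bh(rep(1, 4)), rep(1, 4))
  expect_error(fdr_bh(c(0.5, 1.2)), "\\[0, 1\\]")

  # hand-computed step-up: p (0.005, 0.04, 0.03, 0.9), m = 4
  # sorted: 0.005*4/1 = 0.02; 0.03*4/2 = 0.06; 0.04*4/3 = 0.0533 -> 0.06
  # monotone from the top: 0.02, 0.0533->0.0533? step-up keeps cummin from
  # largest: 0.9, 0.0533, min(0.06, 0.0533) = 0.0533, 0.02
  expect_equal(fdr_bh(c(0.005, 0.04, 0.03, 0.9)),
               c(0.02, 0.0533333333333333, 0.0533333333333333, 0.9),
               tolerance = 1e-12)

  # permutation invariance: adjusted values travel with their p-values
  set.seed(53)
  p <- runif(15)
  perm <- sample(15)
  expect_equal(fdr_bh(p)[perm], fdr_bh(p[perm]))
  # monotone in the sorted order
  adj <- fdr_bh(p)
  expect_true(all(diff(adj[order(p)]) >= 0))
})

test_that("two-sample and paired t-tests match textbook formulas", {
  res <- two_sample_t(c(1, 2, 3), c(4, 5, 6))
  # pooled sd 1, se = sqrt(2/3): t = -3.674
  expect_equal(res$statistic, -3 / sqrt(2 / 3), tolerance = 1e-10)
  expect_equal(res$df, 4)
  expect_equal(res$estimate, -3)

  same <- paired_t(c(1, 5, 3, 8), c(1, 5, 3, 8))
  expect_equal(same$statistic, 0)
  expect_equal(same$p_raw, 1)

  expect_error(paired_t(1, 2), "at least 2")
  expect_error(paired_t(1:3, 1:4), "equal length")
  expect_error(two_sample_t(1, c(2, 3)), "n >= 2")

  # Welch flag changes the df but not the direction
  set.seed(54)
  a <- rnorm(10); b <- rnorm(25, sd = 4)
  pooled <- two_sample_t(a, b); welch <- two_sample_t(a, b, welch = TRUE)
  expect_equal(pooled$df, 33)
  expect_lt(welch$df, 33)
})

test_that("two-way ANOVA matches a hand sums-of-squares table", {
  # balanced 2x2, two observations per cell, additive means + symmetric
  # within-cell spread: interaction SS is exactly zero
  d <- expand.grid(rep = 1:2, A = c("a1", "a2"), B = c("b1", "b2"))
  mu <- c(a1 = 0, a2 = 2); nu <- c(b1 = 0, b2 = 5)
  d$y <- mu[d$A] + nu[d$B] + ifelse(d$rep == 1, -1, 1)
  res <- anova_twoway(d, "y", "A", "B")
  expect_equal(res$estimate[res$name == "A:B"], 0, tolerance = 1e-12)
  expect_equal(res$df, c(1, 1, 1))
  expect_equal(attr(res, "df_residual"), 4)

  # crafted balanced 2x2 vs explicit sums of squares
  d2 <- expand.grid(rep = 1:3, A = c("a1", "a2"), B = c("b1", "b2"))
  set.seed(55)
  d2$y <- rnorm(12)
  res2 <- anova_twoway(d2, "y", "A", "B")
  gm <- mean(d2$y)
  ssa <- sum(tapply(d2$y, d2$A, function(v) length(v) * (mean(v) - gm)^2))
  ssb <- sum(tapply(d2$y, d2$B, function(v) length(v) * (mean(v) - gm)^2))
  cell <- tapply(d2$y, list(d2$A, d2$B), mean)
  ssab <- 3 * sum((sweep(sweep(cell, 1, rowMeans(cell)), 2,
                         colMeans(cell)) + gm)^2)
  sse <- sum((d2$y - ave(d2$y, d2$A, d2$B))^2)
  mse <- sse / 8
  expect_equal(res2$estimate, c(ssa / mse, ssb / mse, (ssab / 1) / mse),
               tolerance = 1e-9)

  expect_error(anova_twoway(data.frame(y = 1:4, A = "a", B = c("x", "y")),
                            "y", "A", "B"), "fewer than 2")
  d3 <- d2[!(d2$A == "a1" & d2$B == "b1"), ]
  expect_error(anova_twoway(d3, "y", "A", "B"), "empty design cell")
})
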