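test_that("zscore standardizes to mean 0, sd 1 (ddof 1) and rejects constants", {
  z <- zscore(c(1, 2, 3))
  expect_equal(as.numeric(z), c(-1, 0, 1))
  set.seed(3)
  x <- rnorm(40, 10, 4)
  z2 <- zscore(x)
  expect_equal(mean(z2), 0, tolerance = 1e-12)
  expect_equal(sd(z2), 1, tolerance = 1e-12)
  expect_equal(attr(z2, "mean"), mean(x))
  expect_error(zscore(c(5, 5, 5)), "constant")
  expect_error(zscore(1), "at least 2")
})

test_that("residualize matches the normal-equations closed form", {
  # exact linear relation -> zero residuals
  x <- c(1, 2, 3, 4)
  expect_equal(residualize(2 * x + 1, x), rep(0, 4), tolerance = 1e-12)
  # orthogonal centered predictor -> residuals are y - mean(y)
  x2 <- c(-1, 1, -1, 1)
  y2 <- c(-2, -2, 2, 2)
  expect_equal(residualize(y2, x2), y2 - mean(y2), tolerance = 1e-12)
  # random fixtures vs (X'X)^{-1} X'y computed independently
  set.seed(5)
  for (i in 1:10) {
    x3 <- rnorm(20)
    y3 <- 0.7 * x3 + rnorm(20)
    X <- cbind(1, x3)
    beta <- solve(t(X) %*% X, t(X) %*% y3)
    expect_equal(residualize(y3, x3), drop(y3 - X %*% beta), tolerance = 1e-10)
    r <- residualize(y3, x3)
    expect_lt(abs(sum(r)), 1e-10)
    expect_lt(abs(sum(r * x3)), 1e-8)  # orthogonal to the predictor
  }
  expect_error(residualize(1:5, rep(2, 5)), "constant")
})

test_that("pearson correlation matches the covariance-formula oracle", {
  expect_equal(pearson_cor(1:10, 3 * (1:10))$estimate, 1)
  expect_equal(pearson_cor(1:10, -(1:10))$estimate, -1)
  set.seed(8)
  x <- rnorm(30)
  y <- 0.4 * x + rnorm(30)
  res <- pearson_cor(x, y)
  r_hand <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(res$estimate, r_hand, tolerance = 1e-12)
  t_hand <- r_hand * sqrt(28 / (1 - r_hand^2))
  expect_equal(res$statistic, t_hand, tolerance = 1e-10)
  expect_equal(res$df, 28)
  expect_equal(res$p, 2 * pt(-abs(t_hand), 28), tolerance = 1e-12)
  expect_error(pearson_cor(rep(1, 5), 1:5), "constant")
})

test_that("paired t follows the hand formula with Cohen's d", {
  s <- paired_sample(value_cs = c(3, 1, 3, 1), value_te = c(2, 2, 2, 2),
                     direction = rep("a-b", 4))
  expect_equal(paired_t(s)$statistic, 0)  # alternating +a/-a differences
  set.seed(13)
  cs <- rnorm(8)
  te <- rnorm(8)
  s2 <- paired_sample(cs, te, rep("a-b", 8))
  res <- paired_t(s2)
  d <- cs - te
  expect_equal(res$statistic, mean(d) / (sd(d) / sqrt(8)), tolerance = 1e-12)
  expect_equal(res$df, 7)
  expect_equal(res$effect, mean(d) / sd(d), tolerance = 1e-12)
  expect_equal(res$p, 2 * pt(-abs(res$statistic), 7), tolerance = 1e-12)
  con <- paired_sample(c(1, 2, 3), c(0, 1, 2), rep("a-b", 3))
  expect_error(paired_t(con), "zero-variance")
})

test_that("split-plot ANOVA reproduces printed df conventions", {
  set.seed(2)
  mk <- function(n1, n2) {
    n <- n1 + n2
    paired_sample(rnorm(n), rnorm(n), rep(c("d1", "d2"), c(n1, n2)))
  }
  res <- mixed_anova_2x2(mk(909, 2839))
  expect_equal(res$interaction$df, c(1, 3746))
  res2 <- mixed_anova_2x2(mk(258, 623))
  expect_equal(res2$interaction$df, c(1, 879))
  expect_equal(res2$switching$df, c(1, 879))
  expect_equal(res2$direction$df, c(1, 879))
})

test_that("interaction F equals the squared two-sample t on per-item differences", {
  set.seed(31)
  for (i in 1:8) {
    n1 <- sample(5:40, 1)
    n2 <- sample(5:40, 1)
    cs <- rnorm(n1 + n2, sd = 1.3)
    te <- rnorm(n1 + n2)
    dirs <- rep(c("d1", "d2"), c(n1, n2))
    s <- paired_sample(cs, te, dirs)
    res <- mixed_anova_2x2(s)
    # independently coded pooled two-sample t on d = cs - te
    d <- cs - te
    d1 <- d[dirs == "d1"]
    d2 <- d[dirs == "d2"]
    sp2 <- ((n1 - 1) * var(d1) + (n2 - 1) * var(d2)) / (n1 + n2 - 2)
    t_pool <- (mean(d1) - mean(d2)) / sqrt(sp2 * (1 / n1 + 1 / n2))
    expect_equal(res$interaction$statistic, t_pool^2, tolerance = 1e-8)
  }
  one_dir <- paired_sample(rnorm(4), rnorm(4), rep("d1", 4))
  expect_error(mixed_anova_2x2(one_dir), "2 directions")
})

test_that("sign test reproduces the two-cell chi-square without correction", {
  res <- sign_test(595, 314)
  expect_equal(res$statistic, (595 - 314)^2 / 909, tolerance = 1e-12)
  expect_equal(res$df, 1)
  expect_equal(res$p, pchisq(res$statistic, 1, lower.tail = FALSE))
  expect_equal(sign_test(7, 7)$statistic, 0)
  expect_error(sign_test(0, 0), "at least 1")
})

test_that("logistic fit matches the Newton-Raphson oracle and flags separation", {
  set.seed(44)
  x <- rnorm(300)
  y <- rbinom(300, 1, plogis(-0.2 + 0.8 * x))
  res <- logistic_fit(y, x)
  orc <- oracle_logistic(y, x)
  expect_equal(res$estimate, orc$beta[[2]], tolerance = 1e-6)
  expect_equal(res$intercept, orc$beta[[1]], tolerance = 1e-6)
  expect_equal(res$se, sqrt(orc$vcov[2, 2]), tolerance = 1e-6)
  expect_equal(res$statistic, (orc$beta[[2]] / sqrt(orc$vcov[2, 2]))^2,
               tolerance = 1e-5)
  expect_true(res$converged)
  # Cox-Snell R2 from independently computed log-likelihoods
  ll <- function(beta) sum(y * log(plogis(beta[1] + beta[2] * x)) +
                             (1 - y) * log(1 - plogis(beta[1] + beta[2] * x)))
  p0 <- mean(y)
  ll0 <- sum(y * log(p0) + (1 - y) * log(1 - p0))
  expect_equal(res$r2_coxsnell, 1 - exp((2 / 300) * (ll0 - ll(orc$beta))),
               tolerance = 1e-6)

  # balanced symmetric fixture -> slope ~ 0
  xb <- c(-2, -1, 1, 2, -2, -1, 1, 2)
  yb <- c(0, 1, 0, 1, 1, 0, 1, 0)
  expect_lt(abs(logistic_fit(yb, xb)$estimate), 1e-8)

  # parameter recovery at n = 5000
  set.seed(99)
  x5 <- rnorm(5000)
  y5 <- rbinom(5000, 1, plogis(0.1 - 0.5 * x5))
  expect_lt(abs(logistic_fit(y5, x5)$estimate - (-0.5)), 0.1)

  # perfect separation flagged, not silent
  sep <- logistic_fit(c(0, 0, 0, 1, 1, 1), c(1, 2, 3, 10, 11, 12))
  expect_false(sep$converged)
  expect_error(logistic_fit(c(1, 1, 1, 1), 1:4), "both classes")
})

test_that("paired t holds its nominal type-I error under the null", {
  pvals <- vapply(1:400, function(s) {
    paired_t(generate_paired_sample(30, delta = 0, sigma = 1, seed = s))$p
  }, 0)
  rate <- mean(pvals < 0.05)
  expect_gt(rate, 0.02)
  expect_lt(rate, 0.09)
})
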