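test_that("Pearson correlation matches hand computation and exchangeability", {
  expect_equal(pearson(1:10, 2 * (1:10) + 1)$r, 1)
  r <- pearson(c(1, 2, 3), c(1, 3, 2))
  expect_equal(r$r, 0.5)
  expect_equal(r$n, 3)
  # p-value from the t transform agrees with the reference implementation
  ref <- cor.test(c(1, 2, 3), c(1, 3, 2))
  expect_equal(r$p, ref$p.value)
  set.seed(8)
  x <- rnorm(20); y <- rnorm(20)
  perm <- sample(20)
  expect_equal(pearson(x, y)$r, pearson(x[perm], y[perm])$r)
  expect_error(pearson(rep(1, 5), rnorm(5)), "variance")
  expect_error(pearson(1:2, 1:2), "at least 3")
})

test_that("partial correlation equals the two-regression residual oracle", {
  set.seed(15)
  n <- 40
  z <- data.frame(z1 = rnorm(n), z2 = rnorm(n))
  x <- 0.5 * z$z1 + rnorm(n)
  y <- -0.3 * z$z2 + 0.4 * x + rnorm(n)
  res <- partial_pearson(x, y, z)
  # oracle: residualize each variable on the covariates, correlate
  rx <- residuals(lm(x ~ z1 + z2, data = z))
  ry <- residuals(lm(y ~ z1 + z2, data = z))
  r_oracle <- cor(rx, ry)
  expect_equal(res$r, r_oracle)
  t_oracle <- r_oracle * sqrt((n - 4) / (1 - r_oracle^2))
  expect_equal(res$p, 2 * pt(-abs(t_oracle), n - 4))
})

test_that("partial correlation degenerates predictably", {
  set.seed(16)
  x <- rnorm(30); y <- rnorm(30)
  # covariate uncorrelated by construction: orthogonalized noise
  z <- residuals(lm(rnorm(30) ~ x + y))
  expect_equal(partial_pearson(x, y, data.frame(z = z))$r, pearson(x, y)$r,
               tolerance = 1e-10)
  # empty covariate set is the zero-order correlation
  empty <- partial_pearson(x, y, data.frame()[seq_along(x), , drop = FALSE])
  expect_equal(empty$r, pearson(x, y)$r)
  expect_equal(empty$kind, "partial")
  # outcome identical to a covariate: residuals collapse
  expect_error(partial_pearson(x, x, data.frame(z = x)), "collapse")
  # collinear covariates
  expect_error(partial_pearson(x, y, data.frame(a = z, b = 2 * z)),
               "collinear")
})

test_that("limits of agreement reconstruct from mean and SD of differences", {
  set.seed(23)
  a <- rnorm(30, 10, 2); b <- a + rnorm(30, 0.4, 0.8)
  ba <- bland_altman(a, b)
  expect_equal(ba$mean_diff, mean(a - b))
  expect_equal(ba$sd_diff, sd(a - b))
  expect_equal(ba$loa_low, ba$mean_diff - 1.96 * ba$sd_diff)
  expect_equal(ba$loa_high, ba$mean_diff + 1.96 * ba$sd_diff)
  # antisymmetry about the bias
  expect_equal(ba$loa_high - ba$mean_diff, ba$mean_diff - ba$loa_low)
  # trend: slope and correlation p-values coincide
  fit <- lm(I(a - b) ~ I((a + b) / 2))
  expect_equal(ba$trend_slope, unname(coef(fit)[2]))
  expect_equal(ba$trend_p, summary(fit)$coefficients[2, 4])
})

test_that("comparing a method with itself gives zero bias and width", {
  a <- c(1.2, 3.4, 5.6, 7.8)
  ba <- bland_altman(a, a)
  expect_equal(ba$mean_diff, 0)
  expect_equal(ba$loa_low, 0)
  expect_equal(ba$loa_high, 0)
  expect_equal(ba$trend_slope, 0)
})

test_that("compliance percentages are reported to one decimal", {
  expect_equal(compliance(122, 140)$pct, 87.1)
  expect_equal(compliance(133, 140)$pct, 95.0)
  expect_equal(compliance(140, 140)$pct, 100.0)
  expect_equal(compliance(rep(c(TRUE, FALSE), c(3, 1)))$pct, 75.0)
  expect_error(compliance(5, 0), "positive")
})

test_that("outlier screen flags only one-sided high extremes", {
  expect_length(flag_outliers(rep(2.5, 10)), 0)   # zero SD: nothing to flag
  set.seed(31)
  v <- c(rnorm(19), 10)
  expect_equal(flag_outliers(v), 20L)
  expect_length(flag_outliers(v, k_sd = Inf), 0)
  expect_length(flag_outliers(c(rnorm(19), -10)), 0)  # low tail not flagged
  expect_error(flag_outliers(c(1, 2)), "at least 3")
})
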