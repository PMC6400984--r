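test_that("normality screening follows the Shapiro-Wilk contract", {
  set.seed(15)
  x <- rnorm(100)
  expect_equal(normality_test(x), stats::shapiro.test(x)$p.value,
               tolerance = 1e-12)
  # a strongly bimodal two-point sample is rejected
  bimodal <- c(rnorm(25, -4, 0.1), rnorm(25, 4, 0.1))
  expect_lt(normality_test(bimodal), 0.05)
  expect_error(normality_test(c(1, 2)), "at least 3")
  expect_error(normality_test(rep(2, 10)), "constant")
})

test_that("combined indices implement the four predictor families", {
  tab <- data.frame(Abd_L = c(0.90, 0.95), Abd_P = c(0.06, 0.02))
  vi <- c(0.5, 0.4)
  expect_identical(combined_index(vi, tab, "plain"), vi)
  expect_equal(combined_index(vi, tab, "L"), vi * tab$Abd_L)
  expect_equal(combined_index(vi, tab, "P"), vi * tab$Abd_P)
  expect_equal(combined_index(vi, tab, "LP")[1], 0.5 * 0.84,
               tolerance = 1e-12)
  # abundance closure: VI splits exactly into leaf, panicle and soil parts
  soil <- 1 - tab$Abd_L - tab$Abd_P
  expect_equal(combined_index(vi, tab, "L") + combined_index(vi, tab, "P") +
                 vi * soil, vi, tolerance = 1e-12)
  expect_error(combined_index(vi, data.frame(x = 1:2), "L"), "Abd_L")
})

test_that("correlation analysis matches the textbook formula", {
  set.seed(33)
  y <- rnorm(23, 3.6, 0.4)
  x <- 0.5 * y + rnorm(23, 0, 0.2)
  out <- correlate(y, list(x = x, self = y, anti = -y))
  r_oracle <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(out$r[out$predictor == "x"], r_oracle, tolerance = 1e-12)
  expect_equal(out$r[out$predictor == "self"], 1)
  expect_equal(out$r[out$predictor == "anti"], -1)
  expect_identical(out$stars[out$predictor == "self"], "**")
  # invariance under positive affine transforms of the predictor
  out2 <- correlate(y, list(x = 10 * x + 3))
  expect_equal(out2$r, r_oracle, tolerance = 1e-12)
  expect_error(correlate(y, list(flat = rep(1, 23))), "zero variance")
})

test_that("simple regression reports the documented summaries", {
  f <- fit_linear(1:10, 2 * (1:10) + 1)
  expect_equal(f$slope, 2, tolerance = 1e-12)
  expect_equal(f$intercept, 1, tolerance = 1e-12)
  expect_equal(f$r_squared, 1, tolerance = 1e-12)
  expect_equal(f$rmse, 0, tolerance = 1e-10)
  set.seed(44)
  for (rep in 1:10) {
    n <- sample(8:30, 1)
    x <- rnorm(n)
    y <- 1.5 * x + rnorm(n)
    f <- fit_linear(x, y)
    X <- cbind(1, x)
    beta <- solve(t(X) %*% X, t(X) %*% y)  # independent normal equations
    expect_equal(c(f$intercept, f$slope), as.numeric(beta), tolerance = 1e-10)
    resid <- y - X %*% beta
    expect_equal(f$rmse, sqrt(mean(resid^2)), tolerance = 1e-10)
    expect_equal(f$pearson_r^2, f$r_squared, tolerance = 1e-12)
    expect_equal(f$pearson_r, cor(x, y), tolerance = 1e-10)
    expect_equal(f$adjusted_r2,
                 1 - (1 - f$r_squared) * (n - 1) / (n - 2), tolerance = 1e-12)
    expect_equal(f$p_value, stats::cor.test(x, y)$p.value, tolerance = 1e-9)
  }
  expect_error(fit_linear(rep(1, 5), rnorm(5)), "singular")
})

test_that("leave-one-out aggregation equals a brute-force enumeration", {
  set.seed(55)
  x <- rnorm(23, 0.25, 0.05)
  y <- 10 * x + rnorm(23, 0, 0.3)
  cv <- loocv_fit(x, y)
  expect_equal(cv$K, 23)
  expect_length(cv$fold_errors, 23)
  # plainly coded double loop with lm()
  co <- matrix(NA_real_, 23, 2)
  r2 <- err <- numeric(23)
  for (i in 1:23) {
    fit <- lm(y[-i] ~ x[-i])
    co[i, ] <- rev(unname(coef(fit)))
    r2[i] <- summary(fit)$r.squared
    err[i] <- unname(coef(fit)[1] + coef(fit)[2] * x[i]) - y[i]
  }
  expect_equal(unname(cv$fold_coefficients), co, tolerance = 1e-12)
  expect_equal(cv$slope, mean(co[, 1]), tolerance = 1e-12)
  expect_equal(cv$intercept, mean(co[, 2]), tolerance = 1e-12)
  expect_equal(cv$r_squared, mean(r2), tolerance = 1e-12)
  expect_equal(cv$rmse, sqrt(mean(err^2)), tolerance = 1e-12)
})

test_that("noiseless linear data gives perfect cross-validation", {
  x <- seq(0.1, 1, length.out = 10)
  cv <- loocv_fit(x, 2 * x + 1)
  expect_equal(unname(cv$fold_coefficients[, 1]), rep(2, 10),
               tolerance = 1e-9)
  expect_equal(unname(cv$fold_coefficients[, 2]), rep(1, 10),
               tolerance = 1e-9)
  expect_equal(cv$rmse, 0, tolerance = 1e-9)
  expect_equal(cv$r_squared, 1, tolerance = 1e-12)
  expect_error(loocv_fit(1:3, 1:3), "at least 4")
})

test_that("the model grid is complete and sorted by adjusted R2", {
  set.seed(66)
  tab <- data.frame(plot_id = paste0("P", 1:12),
                    yield = rnorm(12, 3.6, 0.4),
                    NDVI = runif(12, 0.5, 0.9),
                    NDRE = runif(12, 0.2, 0.4),
                    Abd_L = runif(12, 0.85, 0.98),
                    Abd_P = runif(12, 0.01, 0.2))
  out <- rank_models(tab, c("NDVI", "NDRE"))
  expect_equal(nrow(out), 8)
  expect_true(!is.unsorted(rev(out$adjusted_r2)))
  sub <- rank_models(tab, "NDVI", modes = c("plain", "LP"),
                     exclude_plots = c("P1", "P2"))
  expect_equal(nrow(sub), 2)
})
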