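test_that("acceleration is the residual from the cohort's own age trend", {
  a <- c(22, 31, 38, 45, 52)
  expect_equal(age_acceleration(a, a)$residual, rep(0, 5))
  # deviation from the fit, not from the identity line
  expect_equal(age_acceleration(2 * a + 5, a)$residual, rep(0, 5))
  expect_error(age_acceleration(a, rep(30, 5)), "constant")
})

test_that("acceleration residuals match a normal-equations oracle", {
  chron <- c(20, 25, 33, 41, 50)
  dnam <- c(24, 23, 36, 43, 55)
  # oracle: solve (X'X) b = X'y directly
  X <- cbind(1, chron)
  b <- solve(t(X) %*% X, t(X) %*% dnam)
  res <- age_acceleration(dnam, chron)
  expect_equal(res$residual, as.numeric(dnam - X %*% b), tolerance = 1e-10)
  expect_equal(res$slope, unname(b[2, 1]), tolerance = 1e-10)
  # residuals sum to zero and are orthogonal to the regressor
  expect_lt(abs(sum(res$residual)), 1e-8)
  expect_lt(abs(sum(res$residual * chron)), 1e-8)
})

test_that("adjusted acceleration removes age, sex and BMI structure", {
  set.seed(10)
  n <- 1000
  chron <- runif(n, 20, 55)
  sex <- rep(c("male", "female"), n / 2)
  bmi <- rnorm(n, 50, 8)
  dnam <- chron + 3 * (sex == "female") + 0.2 * bmi + rnorm(n, 0, 4)
  adj <- adjusted_acceleration(dnam, chron, sex, bmi)
  expect_lt(abs(cor(adj, bmi)), 0.05)
  expect_lt(abs(cor(adj, as.numeric(sex == "female"))), 0.05)
  expect_lt(abs(cor(adj, chron)), 0.05)
  # zero-noise additive model: residuals all zero
  dnam0 <- chron + 3 * (sex == "female") + 0.2 * bmi
  expect_equal(adjusted_acceleration(dnam0, chron, sex, bmi), rep(0, n),
               tolerance = 1e-9)
  expect_error(adjusted_acceleration(dnam, chron, rep("male", n), bmi),
               "constant")
})

test_that("pearson_test matches the direct formula", {
  expect_equal(pearson_test(1:10, 1:10)$r, 1)
  # constructed orthogonal fixture
  x <- c(1, 2, 3); y <- c(1, -2, 1)
  expect_equal(pearson_test(x, y)$r, 0)
  # 6-point fixture vs brute-force formula evaluation
  x6 <- c(2.1, 3.4, 1.9, 5.6, 4.4, 3.0)
  y6 <- c(10, 14, 9, 17, 18, 11)
  r_oracle <- sum((x6 - mean(x6)) * (y6 - mean(y6))) /
    sqrt(sum((x6 - mean(x6))^2) * sum((y6 - mean(y6))^2))
  t_oracle <- r_oracle * sqrt(4 / (1 - r_oracle^2))
  p_oracle <- 2 * pt(-abs(t_oracle), df = 4)
  res <- pearson_test(x6, y6)
  expect_equal(res$r, r_oracle, tolerance = 1e-12)
  expect_equal(res$p, p_oracle, tolerance = 1e-12)
  expect_error(pearson_test(rep(1, 5), 1:5), "zero variance")
})

test_that("required correlation for power matches the study's numbers", {
  expect_equal(round(required_r_for_power(52, 0.8, 0.05), 2), 0.38)
  expect_equal(round(required_r_for_power(24, 0.8, 0.05), 3), 0.545)
  expect_lt(required_r_for_power(1e6, 0.8, 0.05), 0.005)
  # strictly decreasing in n, increasing in power
  ns <- c(10, 20, 50, 100, 500)
  expect_true(all(diff(required_r_for_power(ns)) < 0))
  expect_gt(required_r_for_power(52, 0.9), required_r_for_power(52, 0.8))
  expect_error(required_r_for_power(3), ">= 4")
})

test_that("the Fisher z threshold agrees with Monte-Carlo power", {
  # independent oracle: simulate bivariate normals at the claimed detectable
  # correlation and check the rejection rate is close to the target power
  rho <- required_r_for_power(24, 0.8, 0.05)
  set.seed(123)
  rej <- replicate(3000, {
    x <- rnorm(24)
    y <- rho * x + sqrt(1 - rho^2) * rnorm(24)
    cor.test(x, y)$p.value < 0.05
  })
  expect_lt(abs(mean(rej) - 0.8), 0.05)
})

test_that("multivariate fit equals the normal-equations solution", {
  set.seed(3)
  n <- 40
  chron <- runif(n, 20, 55); bmi <- rnorm(n, 50, 8)
  sex <- rep(c("male", "female"), n / 2); mets <- rbinom(n, 1, 0.5) == 1
  dnam <- 0.8 * chron + 0.15 * bmi + 2 * (sex == "female") + rnorm(n, 0, 5)
  fit <- multivariate_fit(dnam, chron, bmi, sex, mets)
  X <- cbind(1, chron, bmi, as.numeric(sex == "female"), as.numeric(mets))
  b <- solve(t(X) %*% X, t(X) %*% dnam)
  expect_equal(fit$estimate, as.numeric(b), tolerance = 1e-8)
  # CI brackets the estimate; adjusted R2 <= 1
  expect_true(all(fit$ci_low < fit$estimate & fit$estimate < fit$ci_high))
  expect_lte(attr(fit, "adj_r2"), 1)
  # zero-noise linear response: adjusted R2 = 1
  dnam0 <- 0.8 * chron + 0.15 * bmi
  fit0 <- suppressWarnings(multivariate_fit(dnam0, chron, bmi, sex))
  expect_equal(attr(fit0, "adj_r2"), 1, tolerance = 1e-10)
  # rank-deficient design is refused
  expect_error(multivariate_fit(dnam, chron, chron, sex), "aliased|deficient")
})

test_that("null responses give approximately uniform p-values", {
  set.seed(8)
  n <- 60
  chron <- runif(n, 20, 55); bmi <- rnorm(n, 50, 8)
  sex <- rep(c("male", "female"), n / 2)
  p_bmi <- replicate(400, {
    fit <- multivariate_fit(rnorm(n), chron, bmi, sex)
    fit$p[fit$term == "bmi"]
  })
  expect_gt(ks.test(p_bmi, "punif")$p.value, 0.01)
  expect_lt(abs(mean(p_bmi < 0.05) - 0.05), 0.035)
})

test_that("years per 10 BMI units supports both documented conventions", {
  fit <- structure(
    data.frame(term = c("(Intercept)", "chron_age", "bmi"),
               estimate = c(1, 0.87, 0.16), se = 0.1, ci_low = 0, ci_high = 2,
               p = 0.05),
    class = c("ols_fit", "data.frame"))
  expect_equal(years_per_10bmi(fit, "simple"), 1.6)
  expect_equal(round(years_per_10bmi(fit, "age_normalized"), 2), 1.84)
  fit$estimate[3] <- 0.24; fit$estimate[2] <- 0.80
  expect_equal(years_per_10bmi(fit, "age_normalized"), 3.0)
  fit$estimate[3] <- 0
  expect_equal(years_per_10bmi(fit, "simple"), 0)
  expect_equal(years_per_10bmi(fit, "age_normalized"), 0)
  fit$estimate[2] <- 0
  expect_error(years_per_10bmi(fit, "age_normalized"), "zero")
})

test_that("percentile trimming excludes the boundary strictly", {
  cohort <- data.frame(chron_age = 1:100)
  trimmed <- percentile_trim(cohort, 0.10, 0.90)
  expect_equal(nrow(trimmed), 80)
  expect_equal(range(trimmed$chron_age), c(11, 90))
  expect_equal(nrow(percentile_trim(cohort, 0, 1)), 98)
  # tie-heavy fixture vs a sort-and-count oracle
  set.seed(2)
  x <- sample(rep(c(20, 25, 25, 30, 30, 30, 40, 55), 6))
  dat <- data.frame(chron_age = x)
  q <- quantile(x, c(0.1, 0.9), type = 7)
  oracle <- x[x > q[1] & x < q[2]]
  trimmed2 <- percentile_trim(dat, 0.1, 0.9)
  expect_equal(sort(trimmed2$chron_age), sort(oracle))
  expect_error(percentile_trim(data.frame(chron_age = rep(5, 10)), 0.1, 0.9),
               "no subjects")
})

test_that("group comparison reproduces the textbook t statistic", {
  g1 <- c(2.0, 3.1, 1.4, 2.5); g2 <- c(-1.2, 0.3, -0.8, -2.0)
  values <- c(g1, g2); group <- rep(c("men", "women"), each = 4)
  # oracle: pooled-variance formula
  sp2 <- (3 * var(g1) + 3 * var(g2)) / 6
  t_oracle <- (mean(g1) - mean(g2)) / sqrt(sp2 * (1 / 4 + 1 / 4))
  p_oracle <- 2 * pt(-abs(t_oracle), df = 6)
  res <- compare_groups(values, group)
  expect_equal(abs(res$t), abs(t_oracle), tolerance = 1e-12)
  expect_equal(res$p, p_oracle, tolerance = 1e-12)
  expect_equal(unname(res$group_means), c(mean(g1), mean(g2)))
  # identical groups: t = 0, p = 1
  same <- compare_groups(c(g1, g1), group)
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)
  # well-separated normals at large n
  set.seed(4)
  big <- compare_groups(c(rnorm(200), rnorm(200, 2)),
                        rep(c("a", "b"), each = 200))
  expect_lt(big$p, 1e-3)
})
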