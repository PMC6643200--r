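test_that("weighted mean matches the closed form and validates inputs", {
  expect_equal(weighted_mean(c(1, 3), c(1, 1)), 2)
  expect_equal(weighted_mean(c(1, 3), c(3, 1)), 1.5)
  expect_error(weighted_mean(1:3, 1:2), "length")
  expect_error(weighted_mean(1:2, c(-1, 1)), "non-negative")
  expect_error(weighted_mean(1:2, c(0, 0)), "zero")
})

test_that("design validation requires two PSUs per stratum", {
  d <- data.frame(stratum = c(1, 1, 2, 2), psu = c(1, 2, 1, 1), weight = 1)
  expect_error(validate_design(d), "2 PSUs")
  d$psu[4] <- 2
  expect_silent(validate_design(d))
  d$weight[1] <- 0
  expect_error(validate_design(d), "positive")
})

test_that("Taylor SE equals s/sqrt(n) on the iid single-stratum design", {
  set.seed(2)
  x <- rnorm(200, 10, 3)
  d <- iid_design(200)
  expect_equal(taylor_se_mean(x, d), sd(x) / sqrt(200), tolerance = 1e-12)
})

test_that("Rao-Wu replicates preserve totals in expectation", {
  d <- data.frame(stratum = rep(1:4, each = 6),
                  psu = rep(rep(1:3, each = 2), 4),
                  weight = runif(24, 0.5, 2))
  W <- rao_wu_replicates(d, replicates = 400, seed = 3)
  expect_identical(dim(W), c(24L, 400L))
  expect_true(all(W >= 0))
  # E[replicate weight] = original weight
  expect_equal(rowMeans(W), d$weight, tolerance = 0.25)
  # within a stratum of n_h = 3, multipliers come from 2 draws scaled by 3/2
  expect_true(all(W[1:6, ] %in% outer(d$weight[1:6], c(0, 1.5, 3))))
})

test_that("svy_lm reduces to OLS on the iid equal-weight design", {
  set.seed(4)
  n <- 150
  x <- rnorm(n)
  y <- 2 + 3 * x + rnorm(n)
  X <- cbind(`(Intercept)` = 1, x = x)
  fit <- svy_lm(y, X, iid_design(n))
  ols <- lm(y ~ x)
  expect_equal(unname(fit$coefficients), unname(coef(ols)), tolerance = 1e-10)
  expect_equal(fit$df, n - 1)
  expect_true(fit$r_squared > 0.8)
  # sandwich SE is close to the model-based OLS SE under homoskedasticity
  expect_equal(unname(fit$se[2]), summary(ols)$coefficients[2, 2],
               tolerance = 0.15)
})

test_that("svy_lm rejects rank-deficient designs by name", {
  n <- 40
  X <- cbind(`(Intercept)` = 1, a = rep(1, n))
  expect_error(svy_lm(rnorm(n), X, iid_design(n)), "aliased terms: a")
})

test_that("Wald test is calibrated against the t-test in one dimension", {
  set.seed(5)
  n <- 120
  x <- rnorm(n)
  y <- 1 + 0 * x + rnorm(n)
  fit <- svy_lm(y, cbind(`(Intercept)` = 1, x = x), iid_design(n))
  w <- wald_test(fit, "x")
  expect_equal(w$df1, 1)
  expect_equal(w$p, unname(fit$p[2]), tolerance = 1e-10)
  expect_error(wald_test(fit, "nope"), "unknown terms")
})

test_that("bootstrap SE agrees with Taylor SE on a clustered design", {
  set.seed(6)
  n <- 240
  d <- data.frame(stratum = rep(1:6, each = 40),
                  psu = rep(rep(1:4, each = 10), 6),
                  weight = 1)
  cluster_fx <- rnorm(24, 0, 0.8)[rep(1:24, each = 10)]
  x <- 5 + cluster_fx + rnorm(n)
  bt <- bootstrap_se(function(data, w) weighted_mean(data, w), x, d,
                     replicates = 300, seed = 7)
  expect_equal(bt$se, taylor_se_mean(x, d), tolerance = 0.2)
  expect_true(bt$ci[1, 1] < bt$estimate && bt$estimate < bt$ci[1, 2])
})
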