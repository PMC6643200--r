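test_that("transform round-trips on positive data", {
  set.seed(1)
  x <- rlnorm(500, 1, 0.5)
  spec <- make_transform_spec(x, "boxcox", "dairy")
  expect_equal(spec$delta, 0)
  z <- transform_amount(x, spec)
  expect_equal(mean(z), 0, tolerance = 1e-10)
  expect_equal(var(z), 2, tolerance = 1e-8)
  expect_equal(inverse_transform(z, spec), x, tolerance = 1e-10)
})

test_that("zeros trigger a half-minimum shift and stay invertible", {
  x <- c(0, 0, 0.4, 1.2, 2.5)
  spec <- make_transform_spec(x, "boxcox", "greens_beans")
  expect_equal(spec$delta, 0.2)
  z <- transform_amount(x, spec)
  expect_equal(inverse_transform(z, spec), x, tolerance = 1e-10)
})

test_that("log transform serves the fatty-acid ratio and rejects zeros", {
  x <- exp(rnorm(200, 0.6, 0.2))
  spec <- make_transform_spec(x, "log", "fatty_acids")
  expect_equal(inverse_transform(transform_amount(x, spec), spec), x,
               tolerance = 1e-10)
  expect_error(make_transform_spec(c(0, 1), "log"), "positive")
})

test_that("back-transform clamps below the support at zero", {
  x <- rlnorm(100, 0, 0.3)
  spec <- make_transform_spec(x, "boxcox", "sodium")
  expect_equal(inverse_transform(-1e6, spec), 0)
  expect_true(all(inverse_transform(rnorm(1000, 0, 10), spec) >= 0))
})
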