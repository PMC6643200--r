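test_that("Gauss-Hermite rule integrates known moments exactly", {
  rule <- heiusual:::gh_rule(9)
  expect_equal(sum(rule$weights), 1, tolerance = 1e-12)
  expect_equal(sum(rule$weights * rule$nodes), 0, tolerance = 1e-10)
  expect_equal(sum(rule$weights * rule$nodes^2), 1, tolerance = 1e-10)
  # degree-8 moment of N(0,1) is 7!! = 105; a 9-point rule is exact there
  expect_equal(sum(rule$weights * rule$nodes^8), 105, tolerance = 1e-8)
})

test_that("gh_expect matches the closed-form lognormal mean", {
  m <- matrix(c(0, 0.5, 1, -0.3), 2, 2)
  sd_e <- 0.4
  got <- heiusual:::gh_expect(m, sd_e, exp, heiusual:::gh_rule(9))
  expect_equal(got, exp(m + sd_e^2 / 2), tolerance = 1e-4)
})

test_that("usual-intake draws have the contracted shape and determinism", {
  fx <- small_cohort()
  fit <- fit_me_model(fx$recalls, fx$cohort$covariates,
                      me_config(method = "moments"))
  p1 <- draw_usual(fit, M = 5, seed = 9)
  p2 <- draw_usual(fit, M = 5, seed = 9)
  expect_identical(p1, p2)
  n <- length(unique(fx$recalls$id))
  expect_identical(nrow(p1), n * 5L)
  expect_true(all(c("id", "draw", "energy", "fatty_acids",
                    "empty_calories_kcal") %in% names(p1)))
  expect_silent(validate_profile(p1))
  expect_true(all(p1$energy >= 1))
  amount_cols <- setdiff(intake_variables(),
                         c("fatty_acids", "empty_calories", "energy"))
  for (v in amount_cols) expect_true(all(p1[[v]] >= 0))
})

test_that("usual intake smooths out day-to-day variation", {
  fx <- small_cohort()
  fit <- fit_me_model(fx$recalls, fx$cohort$covariates,
                      me_config(method = "moments"))
  usual <- draw_usual(fit, M = 20, seed = 10)
  # population SD of usual energy is well below the recall-to-recall SD
  expect_lt(sd(usual$energy), sd(fx$recalls$energy))
})

test_that("age/sex standardization fixes age and resamples sex", {
  fx <- small_cohort()
  fit <- fit_me_model(fx$recalls, fx$cohort$covariates,
                      me_config(method = "moments"))
  s0 <- draw_usual(fit, M = 30, seed = 11)
  s1 <- draw_usual(fit, M = 30, seed = 11,
                   standardize = list(age = 41.3, pct_male = 47.76))
  expect_identical(nrow(s0), nrow(s1))
  # standardization changes the distribution (age/sex effects are nonzero)
  expect_false(isTRUE(all.equal(mean(s0$energy), mean(s1$energy),
                                tolerance = 1e-6)))
  expect_error(draw_usual(fit, M = 0), "M")
})
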