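test_that("cohort generation is deterministic and structurally sound", {
  cfg <- cohort_config(n = 120)
  a <- generate_cohort(cfg, seed = 5)
  b <- generate_cohort(cfg, seed = 5)
  expect_identical(a, b)
  expect_identical(nrow(a$covariates), 120L)
  expect_true(all(a$design$weight > 0))
  expect_silent(validate_design(a$design))
  expect_true(all(a$covariates$age >= 18 & a$covariates$age <= 74))
})

test_that("recalls respect the two-recall design and context columns", {
  fx <- small_cohort()
  rec <- fx$recalls
  expect_true(all(table(rec$id) <= 2))
  expect_setequal(unique(rec$sequence), c(1L, 2L))
  expect_true(all(rec$usual_amount %in% c("more", "same", "less")))
  expect_true(is.logical(rec$weekend))
  amount_cols <- setdiff(intake_variables(),
                         c("fatty_acids", "empty_calories", "energy"))
  for (v in amount_cols) expect_true(all(rec[[v]] >= 0))
  expect_true(all(rec$energy >= 300))
})

test_that("episodic zero rates match the probit truth", {
  cfg <- cohort_config(n = 2500, p_second_recall = 1)
  coh <- generate_cohort(cfg, seed = 31)
  rec <- generate_recalls(coh, seed = 31)
  for (v in cfg$episodic) {
    p_zero <- mean(rec[[v]] == 0)
    expected <- 1 - mean(pnorm(coh$truth$probit_eta[, v]))
    se <- sqrt(expected * (1 - expected) / nrow(rec))
    expect_lt(abs(p_zero - expected), 3 * se + 0.005)
  }
})

test_that("true summaries are weighted, bounded, and consistent", {
  fx <- small_cohort()
  tru <- true_summaries(fx$cohort)
  expect_setequal(tru$component$component, hei_components())
  maxp <- hei_standards()$max_points[match(tru$component$component,
                                           hei_standards()$component)]
  expect_true(all(tru$component$mean_score >= 0 &
                    tru$component$mean_score <= maxp))
  expect_true(all(tru$component$pct_at_max >= 0 &
                    tru$component$pct_at_max <= 100))
  expect_equal(tru$total_mean, sum(tru$component$mean_score), tolerance = 1e-8)
})

test_that("config validation rejects malformed inputs", {
  expect_error(cohort_config(n = 0))
  expect_error(cohort_config(sigma_b = c(total_fruit = -1)))
})
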