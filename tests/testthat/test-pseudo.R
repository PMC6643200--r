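fixture_pp <- function(M = 10) {
  fx <- small_cohort()
  fit <- fit_me_model(fx$recalls, fx$cohort$covariates,
                      me_config(method = "moments"))
  list(pp = build_pseudo_population(fit, fx$cohort$design, M = M, seed = 13),
       cohort = fx$cohort)
}

test_that("pseudo-population rows carry scores, design, and split weights", {
  out <- fixture_pp()
  pp <- out$pp
  n <- nrow(out$cohort$covariates)
  expect_s3_class(pp, "pseudo_population")
  expect_identical(nrow(pp$rows), n * 10L)
  expect_true(all(c("stratum", "psu", "weight", "total") %in% names(pp$rows)))
  # each participant's M pseudo-rows share their weight equally
  w_by_id <- tapply(pp$rows$weight, pp$rows$id, sum)
  expect_equal(as.vector(w_by_id[as.character(out$cohort$design$id)]),
               out$cohort$design$weight, tolerance = 1e-10)
  expect_true(all(pp$rows$total >= 0 & pp$rows$total <= 100))
})

test_that("summaries are bounded, additive, and respect subgroups", {
  out <- fixture_pp()
  s <- summarize_pseudo(out$pp)
  expect_setequal(s$component$component, hei_components())
  expect_equal(s$total_mean, sum(s$component$mean_score), tolerance = 1e-8)
  expect_true(all(s$component$pct_at_max >= 0 & s$component$pct_at_max <= 100))
  ids <- out$cohort$covariates$id[out$cohort$covariates$sex == "female"]
  sf <- summarize_pseudo(out$pp, ids = ids)
  expect_true(all(is.finite(sf$component$mean_score)))
  expect_error(summarize_pseudo(out$pp, ids = -1), "empty subgroup")
})

test_that("percent-at-max uses an absolute float tolerance at the boundary", {
  out <- fixture_pp()
  pp <- out$pp
  # plant a row exactly at the maximum minus float dust
  pp$rows <- pp$rows[1:2, ]
  pp$rows$total_fruit <- c(5 - 1e-12, 4.9)
  pp$rows$weight <- 1
  s <- summarize_pseudo(pp)
  expect_equal(s$component$pct_at_max[s$component$component == "total_fruit"],
               50)
})

test_that("missing participants in the design are an error", {
  fx <- small_cohort()
  fit <- fit_me_model(fx$recalls, fx$cohort$covariates,
                      me_config(method = "moments"))
  expect_error(build_pseudo_population(fit, fx$cohort$design[-1, ], M = 2),
               "missing participants")
})
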