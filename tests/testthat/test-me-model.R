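test_that("me_config validates its arguments", {
  cfg <- me_config()
  expect_identical(cfg$method, "gibbs")
  expect_error(me_config(method = "mcmc"))
  expect_error(me_config(prior_weight = -0.1), "prior_weight")
  expect_error(me_config(prior_weight = 1.5), "prior_weight")
})

test_that("episodic components are detected from zero shares", {
  fx <- small_cohort()
  fit <- fit_me_model(fx$recalls, fx$cohort$covariates,
                      me_config(method = "moments"))
  expect_setequal(fit$episodic, cohort_config()$episodic)
})

test_that("moments fit returns a coherent model object", {
  fx <- small_cohort()
  fit <- fit_me_model(fx$recalls, fx$cohort$covariates,
                      me_config(method = "moments"))
  nv <- length(intake_variables())
  d <- nv + length(fit$episodic)
  expect_s3_class(fit, "me_model")
  expect_identical(dim(fit$Sigma_b), c(d, d))
  expect_identical(dim(fit$Sigma_e), c(nv, nv))
  # both covariance estimates are positive semi-definite after projection
  expect_gte(min(eigen(fit$Sigma_b, symmetric = TRUE)$values), -1e-8)
  expect_gte(min(eigen(fit$Sigma_e, symmetric = TRUE)$values), -1e-8)
  expect_identical(rownames(fit$beta)[1], "(Intercept)")
  expect_output(print(fit), "moments")
})

test_that("moments fit recovers the total transformed-scale variance", {
  fx <- small_cohort()
  fit <- fit_me_model(fx$recalls, fx$cohort$covariates,
                      me_config(method = "moments"))
  # the transform targets variance 2; between + within should recover the
  # residual part of it for the always-consumed components
  for (v in setdiff(intake_variables(), fit$episodic)) {
    tot <- fit$Sigma_b[v, v] + fit$Sigma_e[v, v]
    expect_gt(tot, 0.8)
    expect_lt(tot, 2.6)
  }
})

test_that("gibbs fit runs, is deterministic, and refines the moments fit", {
  fx <- small_cohort()
  cfg <- me_config(method = "gibbs", iterations = 150, burn = 50, seed = 3)
  fit1 <- fit_me_model(fx$recalls, fx$cohort$covariates, cfg)
  fit2 <- fit_me_model(fx$recalls, fx$cohort$covariates, cfg)
  expect_equal(fit1$Sigma_b, fit2$Sigma_b)
  expect_identical(fit1$diagnostics$method, "gibbs")
  expect_true(is.logical(fit1$diagnostics$converged))
  expect_gte(min(eigen(fit1$Sigma_b, symmetric = TRUE)$values), -1e-8)
})

test_that("single recalls alone are rejected, mixed designs accepted", {
  fx <- small_cohort()
  rec1 <- fx$recalls[fx$recalls$sequence == 1, ]
  expect_error(fit_me_model(rec1, fx$cohort$covariates,
                            me_config(method = "moments")),
               "repeated recalls")
  # persons 1..50 contribute a single recall, the rest two
  drop2 <- fx$recalls$sequence == 2 & fx$recalls$id <= 50
  fit <- fit_me_model(fx$recalls[!drop2, ], fx$cohort$covariates,
                      me_config(method = "moments"))
  expect_s3_class(fit, "me_model")
})
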