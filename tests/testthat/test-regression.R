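test_that("person_hei averages intake before scoring", {
  rec <- data.frame(
    id = c(1, 1), sequence = c(1, 2),
    energy = c(1000, 3000),
    total_fruit = c(0, 1.6), whole_fruit = 0, total_veg = 0,
    greens_beans = 0, whole_grains = 0, dairy = 0, total_protein = 0,
    seafood_plant_prot = 0,
    pufa_g = 6, mufa_g = 6, sfa_g = 10,
    refined_grains = 10, sodium = 5,
    solid_fat_kcal = 700, added_sugar_kcal = 500, alcohol_g = 0
  )
  ph <- person_hei(rec)
  # averaged intake: 0.8 cup fruit at 2000 kcal -> density 0.4 -> 2.5 points.
  # Averaging per-recall densities instead would give (0 + 0.533)/2 = 0.267.
  expect_equal(ph$total_fruit, 2.5)
  expect_identical(nrow(ph), 1L)
  expect_error(person_hei(rec[0, ]), "at least one recall")
})

test_that("categorical encoding puts the reference level first", {
  d <- data.frame(heritage = c("Cuban", "Mexican", "Dominican"),
                  age = c(30, 40, 50))
  m <- encode_term(d, "heritage")
  expect_false("heritage:Mexican" %in% colnames(m))  # Mexican is the reference
  expect_identical(ncol(m), 2L)
  expect_identical(encode_term(d, "age")[, 1], d$age)
  expect_error(encode_term(d, "nope"), "unknown covariate")
  expect_error(encode_term(data.frame(x = c("a", "a")), "x"), "constant")
})

test_that("regression_spec validates and backward selection keeps forced terms", {
  expect_error(regression_spec(candidates = "age", forced = "sex"), "forced")
  expect_error(regression_spec(alpha_stay = 0), "alpha_stay")

  set.seed(15)
  coh <- generate_cohort(cohort_config(n = 500), seed = 15)
  cv <- coh$covariates
  y <- 60 + 0.2 * (cv$age - 41) + 3 * (cv$sex == "female") + rnorm(500, 0, 6)
  spec <- regression_spec(
    candidates = c("field_center", "heritage", "age", "sex",
                   "smoking", "marital"),
    forced = c("field_center", "heritage"))
  res <- backward_select(y, cv, coh$design, spec)
  expect_true(all(c("field_center", "heritage") %in% res$kept))
  expect_true(all(c("age", "sex") %in% res$kept))
  expect_true(all(c("term", "estimate", "lcl", "ucl", "p") %in%
                    names(res$table)))
  # audit records any drops with their p-values in order
  if (nrow(res$audit) > 0) {
    expect_true(all(res$audit$p_at_drop > spec$alpha_stay))
    expect_identical(res$audit$step, seq_len(nrow(res$audit)))
  }
  # the fitted slope on age is close to the seeded 0.2 per year
  age_row <- res$table[res$table$term == "age", ]
  expect_lt(abs(age_row$estimate - 0.2), 0.1)
})
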