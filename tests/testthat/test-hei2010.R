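test_that("densities are per 1000 kcal and validated", {
  expect_equal(compute_density(1.6, 2000), 0.8)
  expect_equal(compute_density(c(1, 2), c(1000, 1000)), c(1, 2))
  expect_error(compute_density(1, 0))
})

test_that("fatty-acid ratio handles the zero-SFA edge", {
  expect_equal(as.numeric(fatty_acid_ratio(12, 18, 10)), 3)
  r <- fatty_acid_ratio(5, 5, 0)
  expect_true(attr(r, "capped"))
  expect_gt(as.numeric(r), 2.5)  # zero SFA with unsaturated intake: full score
  expect_error(fatty_acid_ratio(0, 0, 0))
})

test_that("empty-calorie share counts alcohol only beyond 13 g/1000 kcal", {
  # below the threshold alcohol contributes nothing
  expect_equal(empty_calorie_share(100, 100, 10, 2000), 10)
  # 36 g at 2000 kcal: 10 g over the threshold, at 7 kcal/g
  expect_equal(empty_calorie_share(100, 100, 36, 2000),
               (200 + 70) / 2000 * 100)
})

test_that("component scoring is linear and clamped", {
  std <- hei_standards()
  sod <- std[std$component == "sodium", ]
  expect_equal(score_component(1.1, sod), 10)   # at the full-score standard
  expect_equal(score_component(0.5, sod), 10)   # below it: still full
  expect_equal(score_component(2.0, sod), 0)    # at the zero anchor
  expect_equal(score_component(3.0, sod), 0)    # beyond it: clamped
  expect_equal(score_component(1.55, sod), 5)   # midpoint
  fruit <- std[std$component == "total_fruit", ]
  expect_equal(score_component(0.4, fruit), 2.5)
  expect_equal(score_component(1.6, fruit), 5)
})

test_that("perfect and worst profiles hit the scale endpoints", {
  s <- score_profile(perfect_profile())
  expect_equal(s$total, 100)
  expect_true(all(s[, hei_components()] ==
                    hei_standards()$max_points[match(hei_components(),
                                                     hei_standards()$component)]))
  expect_equal(score_profile(worst_profile())$total, 0)
})

test_that("scores are invariant to scaling amounts and energy together", {
  p1 <- perfect_profile(2000)
  p1$total_fruit <- 0.6 * 2          # partial credit somewhere
  p2 <- p1
  num <- setdiff(names(p2), character(0))
  p2[num] <- p2[num] * 1.7
  p2$pufa_g <- p1$pufa_g; p2$mufa_g <- p1$mufa_g; p2$sfa_g <- p1$sfa_g
  expect_equal(score_profile(p2)$total, score_profile(p1)$total)
})

test_that("profile validation catches structural problems", {
  p <- perfect_profile()
  expect_error(validate_profile(p[, setdiff(names(p), "dairy")]), "dairy")
  bad <- p; bad$energy <- -1
  expect_error(validate_profile(bad), "energy")
  bad <- p; bad$sodium <- -0.1
  expect_error(validate_profile(bad), "sodium")
  bad <- p[, setdiff(names(p), c("pufa_g", "mufa_g", "sfa_g"))]
  expect_error(validate_profile(bad), "fatty")
})

test_that("adding intake moves adequacy up and moderation down", {
  p <- worst_profile()
  p$total_fruit <- 0.5
  p$sodium <- 3.0
  base <- score_profile(p)
  more_fruit <- p; more_fruit$total_fruit <- 1.0
  expect_gt(score_profile(more_fruit)$total_fruit, base$total_fruit)
  more_sodium <- p; more_sodium$sodium <- 3.6
  expect_lte(score_profile(more_sodium)$sodium, base$sodium)
})
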