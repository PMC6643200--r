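test_that("standards table loads, validates, and sums to 100 points", {
  std <- hei_standards()
  expect_s3_class(std, "data.frame")
  expect_setequal(std$component, hei_components())
  expect_identical(sum(std$max_points), 100)
  expect_identical(validate_standards(std), std)
})

test_that("component order is fixed and complete", {
  comps <- hei_components()
  expect_length(comps, 12)
  expect_identical(comps[1], "total_fruit")
  expect_identical(comps[12], "empty_calories")
  expect_identical(anyDuplicated(comps), 0L)
})

test_that("validate_standards rejects broken tables", {
  std <- hei_standards()
  bad <- std
  bad$max_points[1] <- 10  # valid value, but the total is no longer 100
  expect_error(validate_standards(bad), "100")
  bad$max_points[1] <- 6
  expect_error(validate_standards(bad), "5, 10 or 20")
  bad <- std
  bad$density_at_max[bad$component == "sodium"] <- 3  # above its zero anchor
  expect_error(validate_standards(bad))
  expect_error(validate_standards(std[-1, ]))
})
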