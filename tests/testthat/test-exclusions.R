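toy_roster <- function() {
  data.frame(
    id = 1:6,
    age = c(75, 40, 40, 40, 40, 40),
    heritage = c("Mexican", NA, "other", "Cuban", "Cuban", "Cuban"),
    n_recalls = c(2, 2, 2, 0, 2, 2),
    reliable = c(TRUE, TRUE, TRUE, TRUE, FALSE, TRUE),
    energy_percentile_flag = c("in-range", "in-range", "in-range",
                               "in-range", "in-range", "in-range"),
    stringsAsFactors = FALSE
  )
}

test_that("records are attributed to the first failing criterion", {
  r <- toy_roster()
  # record 3 fails both 'other heritage' and (say) unreliability
  r$reliable[3] <- FALSE
  out <- apply_exclusions(r)
  expect_identical(out$retained, 6L)
  a <- setNames(out$audit$excluded, out$audit$criterion)
  expect_identical(a[["age_ge_74"]], 1L)
  expect_identical(a[["missing_heritage"]], 1L)
  expect_identical(a[["other_mixed_heritage"]], 1L)  # counted once, not twice
  expect_identical(a[["no_recalls"]], 1L)
  expect_identical(a[["unreliable_recalls"]], 1L)
})

test_that("retained plus per-criterion counts partition the roster", {
  out <- apply_exclusions(toy_roster())
  expect_identical(length(out$retained) + sum(out$audit$excluded),
                   nrow(toy_roster()))
})

test_that("filtering is idempotent", {
  out <- apply_exclusions(toy_roster())
  again <- apply_exclusions(out$roster)
  expect_identical(again$retained, out$retained)
  expect_identical(sum(again$audit$excluded), 0L)
})

test_that("energy percentiles are computed per sex when flags are absent", {
  set.seed(9)
  n <- 400
  r <- data.frame(
    id = seq_len(n), age = 40,
    heritage = "Cuban", n_recalls = 2, reliable = TRUE,
    sex = rep(c("male", "female"), n / 2),
    energy = c(rnorm(n / 2, 2300, 400), rnorm(n / 2, 1900, 350)),
    stringsAsFactors = FALSE
  )
  out <- apply_exclusions(r)
  a <- setNames(out$audit$excluded, out$audit$criterion)
  # p1/p99 per sex with type-2 quantiles excludes ~2% per sex
  expect_gte(a[["energy_percentile"]], 4L)
  expect_lte(a[["energy_percentile"]], 12L)
  expect_error(apply_exclusions(r[, setdiff(names(r), c("energy", "sex"))]),
               "energy")
})

test_that("missing required columns raise a named error", {
  expect_error(apply_exclusions(data.frame(id = 1)), "missing columns")
})
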