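toy_counts <- function(...) {
  df <- data.frame(..., stringsAsFactors = FALSE)
  if (!"urban" %in% names(df)) df$urban <- rep(1L, nrow(df))
  df
}

test_that("birthday expansion conserves counts and stays inside the year", {
  counts <- toy_counts(postal_code = c("H3A2T5", "H3A2T5", "K1A0B1"),
                       birth_year = c(2005L, 2004L, 2005L),
                       gender = c("F", "M", "F"),
                       count = c(1L, 3L, 2L))
  persons <- assign_uniform_birthdays(counts, seed = 1L)
  expect_equal(nrow(persons), 6L)
  expect_true(all(format(persons$date_of_birth, "%Y") ==
                    as.character(persons$birth_year)))
  expect_error(assign_uniform_birthdays(transform(counts, count = c(-1L, 3L, 2L))),
               "non-negative")
})

test_that("drawn days of birth are uniform over the year", {
  counts <- toy_counts(postal_code = "H3A2T5", birth_year = 2005L,
                       gender = "F", count = 10000L)
  persons <- assign_uniform_birthdays(counts, seed = 2L)
  doy <- as.integer(format(persons$date_of_birth, "%j"))
  gof <- stats::chisq.test(tabulate(doy, nbins = 365))
  expect_gt(gof$p.value, 0.001)
})

test_that("singleton cells are always unique and year-level results are deterministic", {
  counts <- toy_counts(postal_code = rep(c("H3A2T5", "K1A0B1"), each = 2),
                       birth_year = c(2004L, 2005L, 2004L, 2005L),
                       gender = "F", count = 1L)
  res <- aggregate_uniqueness(counts, generalization_level("year"), R = 5,
                              seed = 3L)
  expect_equal(res$per_code$mean_uniqueness, c(1, 1))
  res2 <- aggregate_uniqueness(counts, generalization_level("year"), R = 50,
                               seed = 99L)
  expect_equal(res$per_code, res2$per_code)
})

test_that("a two-person cell converges to the closed-form collision rate", {
  # one non-leap-year cell of 2: P(unique) = 364/365 per person
  counts <- toy_counts(postal_code = "H3A2T5", birth_year = 2005L,
                       gender = "M", count = 2L)
  R <- 3000L
  res <- aggregate_uniqueness(counts, generalization_level("full"), R = R,
                              seed = 11L)
  p <- 364 / 365
  se <- sqrt(p * (1 - p) / R)
  expect_lte(abs(res$per_code$mean_uniqueness - p), 3 * se)
})

test_that("generalizing the date of birth never raises uniqueness", {
  set.seed(17)
  counts <- toy_counts(postal_code = rep(sprintf("H3A2T%d", 0:4), each = 4),
                       birth_year = rep(2003:2006, 5),
                       gender = rep(c("F", "M"), 10),
                       count = sample(1:12, 20, replace = TRUE))
  u <- sapply(c("full", "month_year", "year"), function(d) {
    aggregate_uniqueness(counts, generalization_level(d), R = 200,
                         seed = 5L)$per_code$mean_uniqueness
  })
  expect_true(all(u[, "full"] >= u[, "month_year"] - 1e-9))
  expect_true(all(u[, "month_year"] >= u[, "year"] - 1e-9))
})

test_that("larger cells cannot raise expected uniqueness", {
  base <- toy_counts(postal_code = "H3A2T5", birth_year = 2005L,
                     gender = "F", count = 5L)
  bigger <- transform(base, count = 25L)
  u_small <- aggregate_uniqueness(base, generalization_level("full"), R = 400,
                                  seed = 7L)$per_code$mean_uniqueness
  u_big <- aggregate_uniqueness(bigger, generalization_level("full"), R = 400,
                                seed = 7L)$per_code$mean_uniqueness
  expect_lt(u_big, u_small)
})

test_that("urban/rural summary reports present strata only", {
  counts <- toy_counts(postal_code = c("H3A2T5", "K1A0B1", "A0A1B2"),
                       birth_year = 2005L, gender = "F",
                       count = c(2L, 3L, 40L),
                       urban = c(1L, 1L, 0L))
  res <- aggregate_uniqueness(counts, generalization_level("year"), R = 2,
                              seed = 1L)
  summ <- urban_rural_summary(res)
  expect_setequal(summ$stratum, c("urban", "rural"))
  # rural codes with much larger cells cannot beat urban at year level
  expect_lte(summ$median_uniqueness[summ$stratum == "rural"],
             summ$median_uniqueness[summ$stratum == "urban"])

  urban_only <- aggregate_uniqueness(counts[1:2, ],
                                     generalization_level("year"), R = 2)
  s2 <- urban_rural_summary(urban_only)
  expect_false("rural" %in% s2$stratum)
  expect_equal(s2$n_codes, 2L)

  single <- aggregate_uniqueness(counts[1, ], generalization_level("full"),
                                 R = 20, seed = 2L)
  s3 <- urban_rural_summary(single)
  expect_equal(s3$median_uniqueness, single$per_code$mean_uniqueness)
})

test_that("degenerate aggregate inputs are rejected", {
  expect_error(aggregate_uniqueness(
    toy_counts(postal_code = character(0), birth_year = integer(0),
               gender = character(0), count = integer(0)),
    generalization_level("year")), "empty|missing")
  dup <- toy_counts(postal_code = c("H3A2T5", "H3A2T5"),
                    birth_year = 2005L, gender = "F", count = 1L)
  expect_error(aggregate_uniqueness(dup, generalization_level("year")),
               "duplicate")
})
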