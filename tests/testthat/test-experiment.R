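test_that("trail-year sampling is uniform and deterministic under a seed", {
  expect_equal(sample_trail_years(1996:2006, 11)$years, 1996:2006)
  expect_error(sample_trail_years(1996:2006, 12), "1..length")

  set.seed(101)
  draws <- replicate(11000, sample_trail_years(1996:2006, 1)$years)
  freq <- tabulate(factor(draws, levels = 1996:2006)) / 11000
  se <- sqrt((1 / 11) * (10 / 11) / 11000)
  expect_true(all(abs(freq - 1 / 11) <= 3 * se))

  a <- with(list(), {set.seed(5); replicate(5, sample_trail_years(1996:2006, 3)$years)})
  b <- with(list(), {set.seed(5); replicate(5, sample_trail_years(1996:2006, 3)$years)})
  expect_identical(a, b)
})

test_that("a full-window trail needs exactly one iteration", {
  reg <- small_encoded_registry(100, seed = 41L)
  res <- run_study_point(reg, generalization_level("year", 1, TRUE),
                         k = 11, seed = 1L)
  expect_equal(res$iterations, 1L)
  trail <- trail_spec(1996:2006)
  keys <- build_quasi_identifiers(reg, generalization_level("year", 1, TRUE), trail)
  expect_equal(res$mean, exact_uniqueness(frequency_spectrum(keys))$value)
})

test_that("zero variance across subsets stops at the minimum iteration count", {
  # everyone shares one key at gender-only generalization with one gender
  trails <- replicate(30, rep("H3A2T5", 11), simplify = FALSE)
  names(trails) <- sprintf("P%02d", 1:30)
  reg <- encode_sentinels(manual_registry(trails, births = rep("1950-01-01", 30)))
  res <- run_study_point(reg, generalization_level("suppressed", 0, TRUE),
                         k = 2, seed = 3L)
  expect_equal(res$mean, 0)
  expect_equal(res$iterations, 10L)
})

test_that("iteration counts stay within the stopping rule's bounds", {
  reg <- small_encoded_registry(400, seed = 43L)
  for (k in c(1L, 3L)) {
    res <- run_study_point(reg, generalization_level("year", 2, TRUE),
                           k = k, seed = k)
    expect_gte(res$iterations, 10L)
    expect_lte(res$iterations, 1000L)
    expect_equal(res$mean, mean(res$values))
    expect_gte(res$mean, 0)
    expect_lte(res$mean, 1)
  }
})

test_that("longer trails and finer generalization never reduce exact uniqueness", {
  reg <- small_encoded_registry(400, seed = 47L)
  u_of <- function(lvl, years) {
    keys <- build_quasi_identifiers(reg, lvl, trail_spec(years))
    exact_uniqueness(frequency_spectrum(keys))$value
  }
  lvl <- generalization_level("year", 4, TRUE)
  # deterministic superset case: full window vs each single year
  u_full <- u_of(lvl, 1996:2006)
  for (y in c(1996, 2001, 2006)) expect_gte(u_full, u_of(lvl, y))
  # coarsening any one component on a fixed trail
  yrs <- c(1997, 2003)
  expect_gte(u_of(generalization_level("full", 4, TRUE), yrs),
             u_of(generalization_level("month_year", 4, TRUE), yrs))
  expect_gte(u_of(generalization_level("month_year", 4, TRUE), yrs),
             u_of(generalization_level("year", 4, TRUE), yrs))
  expect_gte(u_of(generalization_level("year", 4, TRUE), yrs),
             u_of(generalization_level("year", 3, TRUE), yrs))
  expect_gte(u_of(generalization_level("year", 4, TRUE), yrs),
             u_of(generalization_level("year", 4, FALSE), yrs))
})

test_that("youth/adult stratification matches the age rule and calibration", {
  trails <- list(young = rep("H3A2T5", 11), old = rep("K1A0B1", 11))
  reg <- manual_registry(trails, births = c("1990-06-01", "1950-06-01"))
  strat <- stratify_youth_adult(reg, trail_spec(1996))
  expect_equal(strat$youth$person_id, "young")   # age 6
  expect_equal(strat$adult$person_id, "old")
  # adult for any trail in the window
  for (y in list(1996, 2006, c(1996, 2006))) {
    expect_true("old" %in% stratify_youth_adult(reg, trail_spec(y))$adult$person_id)
  }
  # partition is exhaustive and disjoint
  big <- generate_population(synth_config(20000, seed = 53L))
  s <- stratify_youth_adult(big, trail_spec(2001))
  expect_equal(nrow(s$youth) + nrow(s$adult), nrow(big))
  expect_length(intersect(s$youth$person_id, s$adult$person_id), 0)
  # Montreal-profile calibration: youth share near 30%
  expect_lt(abs(nrow(s$youth) / nrow(big) - 0.30), 0.05)
})

test_that("sensitivity bounds reproduce the closed-form extremes", {
  b <- sensitivity_bounds(0.20, 0.06)
  expect_equal(b$u_max, 0.248)
  expect_equal(b$u_min, 0.188)
  expect_equal(sensitivity_bounds(0.05, 0.06)$u_max, 0.107)
  expect_equal(sensitivity_bounds(0.3, 0), list(u_min = 0.3, u_max = 0.3))
  expect_error(sensitivity_bounds(1.2, 0.05), "\\[0, 1\\]")
})

test_that("policy tables flag thresholds with strict implying relaxed", {
  df <- data.frame(mean_uniqueness = c(0.03, 0.05, 0.12, 0.20, 0.50))
  tab <- policy_table(df)
  expect_equal(tab$acceptable_strict, c(TRUE, TRUE, FALSE, FALSE, FALSE))
  expect_equal(tab$acceptable_relaxed, c(TRUE, TRUE, TRUE, TRUE, FALSE))
  expect_true(all(!tab$acceptable_strict | tab$acceptable_relaxed))
  expect_error(policy_thresholds(0.2, 0.05), "strict")
})
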