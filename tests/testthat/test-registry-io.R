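test_that("write -> read round-trips a generated registry", {
  reg <- generate_population(synth_config(150, seed = 17L))
  path <- local_csv()
  write_registry(reg, path)
  back <- read_registry(path)
  expect_equal(nrow(attr(back, "problems")), 0L)
  attr(back, "problems") <- NULL
  expect_equal(as.data.frame(back), as.data.frame(reg))
  expect_equal(registry_window(back), registry_window(reg))
})

test_that("a file missing a window postal column is a hard error", {
  reg <- generate_population(synth_config(20, seed = 1L))
  reg$pc_1996 <- NULL
  df <- as.data.frame(reg)
  df$date_of_death <- ifelse(is.na(df$date_of_death), "",
                             format(df$date_of_death, "%Y-%m-%d"))
  path <- local_csv()
  utils::write.csv(df, path, row.names = FALSE)
  expect_error(read_registry(path, window = 1996:2006), "1996")
  expect_error(read_registry(path, window = 1997:2006), NA)
})

test_that("mandatory columns are required and bad rows are reported", {
  reg <- generate_population(synth_config(5, seed = 2L))
  df <- as.data.frame(reg)
  df$date_of_birth <- as.character(df$date_of_birth)
  df$date_of_death <- ifelse(is.na(df$date_of_death), "",
                             format(df$date_of_death, "%Y-%m-%d"))
  df$date_of_birth[3] <- "not-a-date"
  df$gender[5] <- "X"
  path <- local_csv()
  utils::write.csv(df, path, row.names = FALSE)
  parsed <- read_registry(path)
  expect_equal(nrow(parsed), 3L)
  probs <- attr(parsed, "problems")
  expect_setequal(probs$row, c(3L, 5L))

  df$gender <- NULL
  utils::write.csv(df, path, row.names = FALSE)
  expect_error(read_registry(path), "mandatory")
})

test_that("qc removes all-missing and inconsistent persons, preserving order", {
  trails <- list(
    clean  = rep("H3A2T5", 11),
    empty  = rep("", 11),
    late   = c(rep("H3A2T5", 8), "", "", "K1A0B1"),  # code after death
    early  = c("J4B5C6", rep("", 4), rep("H3A2T5", 6)), # code before birth
    clean2 = rep("K1A0B1", 11))
  reg <- manual_registry(trails,
                         births = c("1950-01-01", "1950-01-01", "1950-01-01",
                                    "2001-06-15", "1980-12-31"),
                         deaths = c(NA, NA, "2003-05-20", NA, NA))
  qc <- qc_filter(reg)
  expect_equal(qc$report$n_input, 5L)
  expect_equal(qc$report$n_removed_missing_all, 1L)
  expect_equal(qc$report$n_removed_inconsistent, 2L)
  expect_equal(qc$registry$person_id, c("clean", "clean2"))
  r <- qc$report
  expect_equal(r$n_input,
               r$n_removed_missing_all + r$n_removed_inconsistent + r$n_retained)
  expect_equal(r$removal_fraction, 3 / 5)
})

test_that("qc is the identity on a clean registry and is idempotent", {
  reg <- generate_population(synth_config(200, seed = 19L))
  qc1 <- qc_filter(reg)
  expect_equal(qc1$report$removal_fraction, 0)
  expect_equal(as.data.frame(qc1$registry), as.data.frame(reg))
  qc2 <- qc_filter(qc1$registry)
  expect_equal(as.data.frame(qc2$registry), as.data.frame(qc1$registry))
  expect_equal(qc2$report$n_retained, qc1$report$n_retained)
})

test_that("sentinel encoding fills exactly the out-of-life years", {
  trails <- list(
    born2000 = c(rep("", 4), rep("H3A2T5", 7)),
    whole    = rep("K1A0B1", 11),
    died2003 = c(rep("J4B5C6", 8), rep("", 3)))
  reg <- manual_registry(trails,
                         births = c("2000-03-01", "1960-01-01", "1940-01-01"),
                         deaths = c(NA, NA, "2003-11-30"))
  enc <- encode_sentinels(qc_filter(reg)$registry)
  expect_equal(unname(unlist(enc[1, paste0("pc_", 1996:1999)])),
               rep(SENTINEL_UNBORN, 4))
  expect_equal(unname(unlist(enc[1, paste0("pc_", 2000:2006)])),
               rep("H3A2T5", 7))
  expect_equal(unname(unlist(enc[3, paste0("pc_", 2004:2006)])),
               rep(SENTINEL_DEAD, 3))
  expect_equal(unname(unlist(enc[3, "pc_2003"])), "J4B5C6")
  # a person alive for the whole window is untouched
  expect_equal(unname(unlist(enc[2, paste0("pc_", 1996:2006)])),
               rep("K1A0B1", 11))
})

test_that("an empty in-life postal value after QC is a contract violation", {
  trails <- list(gap = c(rep("H3A2T5", 5), "", rep("H3A2T5", 5)))
  reg <- manual_registry(trails, births = "1950-01-01")
  expect_error(encode_sentinels(reg), "in-life")
})

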