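# Aggregate-counts uniqueness via uniform birthday redistribution.
#
# When only per-cell population counts (postal code x birth year x gender)
# are available, per-postal-code uniqueness on the basic demographics is
# estimated by repeatedly assigning each person a uniform day of birth
# within their birth year and computing exact uniqueness per code, then
# averaging over repetitions.

validate_aggregate_counts <- function(counts) {
  required <- c("postal_code", "gender", "count")
  missing_cols <- setdiff(required, names(counts))
  if (length(missing_cols)) {
    stop("aggregate counts are missing columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (!"birth_year" %in% names(counts)) {
    if (!"age" %in% names(counts)) {
      stop("aggregate counts need a `birth_year` or `age` column",
           call. = FALSE)
    }
    ref <- attr(counts, "reference_year")
    if (is.null(ref)) {
      stop("an `age` column needs a `reference_year` attribute to convert ",
           "ages to birth years", call. = FALSE)
    }
    counts$birth_year <- as.integer(ref) - as.integer(counts$age)
  }
  if (!nrow(counts)) stop("empty aggregate counts", call. = FALSE)
  if (any(counts$count < 0) || any(counts$count != round(counts$count))) {
    stop("counts must be non-negative integers", call. = FALSE)
  }
  key <- paste(counts$postal_code, counts$birth_year, counts$gender)
  if (anyDuplicated(key)) {
    stop("duplicate (postal_code, birth_year, gender) cells", call. = FALSE)
  }
  if (!"urban" %in% names(counts)) counts$urban <- 1L
  counts
}

#' Expand aggregate counts into persons with uniform birthdays
#'
#' Each cell of `count` persons is expanded into individual records, each
#' given a day of birth drawn uniformly over the calendar days of the
#' cell's birth year (365 or 366).
#'
#' @param counts Aggregate counts with columns `postal_code`,
#'   `birth_year` (or `age` plus a `reference_year` attribute), `gender`,
#'   `count`, and optionally `urban`.
#' @param seed Optional integer seed.
#' @return Data frame of persons with columns `postal_code`, `gender`,
#'   `birth_year`, `date_of_birth` (`Date`), `urban`.
#' @export
assign_uniform_birthdays <- function(counts, seed = NULL) {
  counts <- validate_aggregate_counts(counts)
  with_seed(seed, {
    idx <- rep(seq_len(nrow(counts)), counts$count)
    year <- counts$birth_year[idx]
    nd <- days_in_year(year)
    doy <- 1L + as.integer(floor(stats::runif(length(idx)) * nd))
    data.frame(postal_code = counts$postal_code[idx],
               gender = counts$gender[idx],
               birth_year = year,
               date_of_birth = as.Date(paste0(year, "-01-01")) + (doy - 1),
               urban = counts$urban[idx],
               stringsAsFactors = FALSE)
  })
}

#' Per-postal-code uniqueness from aggregate counts
#'
#' For each repetition, persons in every (postal code, birth year, gender)
#' cell receive uniform random days of birth; exact uniqueness on
#' (generalized DOB, gender) is computed per postal code against the
#' code's own residents, and the per-code mean over repetitions is
#' reported. At `dob_level = "year"` the birthday draws are irrelevant and
#' the result is deterministic.
#'
#' @param counts Aggregate counts (see [assign_uniform_birthdays()]).
#' @param level A [generalization_level()]; `dob_level` must be `"full"`,
#'   `"month_year"` or `"year"`. (Postal code identifies the stratum, so
#'   `postal_chars` is not applied here.)
#' @param R Number of repetitions (default 1000).
#' @param seed Optional integer seed.
#' @param pooled If `TRUE`, a single pooled denominator over all codes is
#'   used instead of per-code denominators.
#' @return An `aggregate_result`: list with `per_code` (data frame
#'   `postal_code`, `urban`, `mean_uniqueness`), `R`, `dob_level`, and for
#'   `pooled = TRUE` also `pooled_mean`.
#' @export
aggregate_uniqueness <- function(counts, level = generalization_level(),
                                 R = 1000L, seed = NULL, pooled = FALSE) {
  stopifnot(inherits(level, "generalization_level"))
  if (!level$dob_level %in% c("full", "month_year", "year")) {
    stop("`dob_level` must be full, month_year or year", call. = FALSE)
  }
  counts <- validate_aggregate_counts(counts)
  counts <- counts[counts$count > 0, , drop = FALSE]
  if (!nrow(counts)) stop("empty aggregate counts", call. = FALSE)
  stop_if_not_scalar_number(R, "R", positive = TRUE)
  R <- as.integer(R)

  code_levels <- unique(counts$postal_code)
  code_of_cell <- match(counts$postal_code, code_levels)
  code_total <- as.numeric(tapply(counts$count, code_of_cell, sum))
  urban <- as.integer(tapply(counts$urban, code_of_cell, function(x) x[1]))
  m <- counts$count
  nd <- days_in_year(counts$birth_year)

  deterministic <- level$dob_level == "year"
  n_reps <- if (deterministic) 1L else R

  with_seed(seed, {
    acc <- numeric(length(code_levels))
    pooled_acc <- 0
    for (rep_i in seq_len(n_reps)) {
      # singles per cell: persons whose drawn DOB value is unique in
      # their (code, year, gender) cell
      singles <- vapply(seq_len(nrow(counts)), function(i) {
        if (m[i] == 1L) return(1L)
        if (deterministic) return(0L)
        n_bins <- if (level$dob_level == "full") nd[i] else 12L
        if (level$dob_level == "full") {
          draws <- sample.int(n_bins, m[i], replace = TRUE)
        } else {
          # month of a uniform day: months weighted by their day counts
          doy <- sample.int(nd[i], m[i], replace = TRUE)
          origin <- as.Date(paste0(counts$birth_year[i], "-01-01"))
          draws <- as.integer(format(origin + (doy - 1), "%m"))
        }
        sum(tabulate(draws, nbins = n_bins) == 1L)
      }, integer(1))
      per_code_uniques <- as.numeric(tapply(singles, code_of_cell, sum))
      per_code_uniques[is.na(per_code_uniques)] <- 0
      acc <- acc + per_code_uniques / code_total
      pooled_acc <- pooled_acc + sum(per_code_uniques) / sum(code_total)
    }
    per_code <- data.frame(postal_code = code_levels,
                           urban = urban,
                           mean_uniqueness = acc / n_reps,
                           stringsAsFactors = FALSE)
    res <- list(per_code = per_code, R = R, dob_level = level$dob_level)
    if (pooled) res$pooled_mean <- pooled_acc / n_reps
    structure(res, class = "aggregate_result")
  })
}

#' @export
print.aggregate_result <- function(x, ...) {
  cat(sprintf("<aggregate_result> %d postal codes, dob=%s, R=%d\n",
              nrow(x$per_code), x$dob_level, x$R))
  invisible(x)
}

#' Urban/rural summary of an aggregate result
#'
#' Median of per-code mean uniqueness within each stratum; strata with no
#' codes are absent from the table.
#'
#' @param result An [aggregate_uniqueness()] result.
#' @return Data frame with columns `stratum`, `n_codes`,
#'   `median_uniqueness`.
#' @export
urban_rural_summary <- function(result) {
  stopifnot(inherits(result, "aggregate_result"))
  pc <- result$per_code
  rows <- lapply(c(urban = 1L, rural = 0L), function(flag) {
    sub <- pc[pc$urban == flag, , drop = FALSE]
    if (!nrow(sub)) return(NULL)
    data.frame(stratum = if (flag == 1L) "urban" else "rural",
               n_codes = nrow(sub),
               median_uniqueness = stats::median(sub$mean_uniqueness),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  rownames(out) <- NULL
  out
}
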