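# Quasi-identifier construction over the generalization lattice.
#
# A generalization level fixes the granularity of each quasi-identifier:
# date of birth (full / month-year / year / suppressed), postal code
# (number of leading characters kept, 0 = suppressed), and whether gender
# is included. A trail spec selects which window years' postal snapshots
# enter the key; keys are year-labelled, so the adversary is assumed to
# know *when* a person lived at each address.

DOB_LEVELS <- c("full", "month_year", "year", "suppressed")

#' Define a generalization level
#'
#' @param dob_level One of `"full"`, `"month_year"`, `"year"`,
#'   `"suppressed"`.
#' @param postal_chars Number of leading postal characters kept, 0..6
#'   (0 suppresses the postal trail entirely).
#' @param include_gender Should gender enter the key?
#' @return An object of class `generalization_level`.
#' @export
generalization_level <- function(dob_level = "full", postal_chars = 6L,
                                 include_gender = TRUE) {
  dob_level <- match.arg(dob_level, DOB_LEVELS)
  if (!is.numeric(postal_chars) || length(postal_chars) != 1 ||
      !(postal_chars %in% 0:6)) {
    stop("`postal_chars` must be an integer in 0..6", call. = FALSE)
  }
  if (dob_level == "suppressed" && postal_chars == 0 && !include_gender) {
    stop("at least one quasi-identifier component must be kept",
         call. = FALSE)
  }
  structure(list(dob_level = dob_level,
                 postal_chars = as.integer(postal_chars),
                 include_gender = isTRUE(include_gender)),
            class = "generalization_level")
}

#' Define a residential-trail specification
#'
#' @param years Calendar years (need not be contiguous); stored sorted.
#' @return An object of class `trail_spec` with fields `years` and `k`.
#' @export
trail_spec <- function(years) {
  years <- as.integer(years)
  if (!length(years) || anyNA(years) || anyDuplicated(years)) {
    stop("`years` must be a non-empty set of distinct calendar years",
         call. = FALSE)
  }
  years <- sort(years)
  structure(list(years = years, k = length(years)), class = "trail_spec")
}

#' Crop a postal code to its first k characters
#'
#' Sentinel codes crop like any other string; they remain distinguishable
#' from real codes because real codes never start with `U` or `D`.
#'
#' @param code Character vector of 6-character codes, sentinels, or `""`.
#' @param k Integer in 0..6; `k = 0` yields `""`.
#' @return Character vector of cropped codes.
#' @export
crop_postal <- function(code, k) {
  if (!is.numeric(k) || length(k) != 1 || !(k %in% 0:6)) {
    stop("`k` must be an integer in 0..6", call. = FALSE)
  }
  bad <- nchar(code) != 6 & code != ""
  if (any(bad)) {
    stop("postal codes must have exactly 6 characters (got '",
         code[which(bad)[1]], "')", call. = FALSE)
  }
  if (k == 0) return(rep("", length(code)))
  substr(code, 1, k)
}

#' Generalize a date of birth
#'
#' @param dob `Date` vector.
#' @param level One of the DOB granularities (`"full"`, `"month_year"`,
#'   `"year"`, `"suppressed"`).
#' @return Character vector: `"YYYY-MM-DD"`, `"YYYY-MM"`, `"YYYY"` or `""`.
#' @export
generalize_dob <- function(dob, level) {
  level <- match.arg(level, DOB_LEVELS)
  switch(level,
         full = format(dob, "%Y-%m-%d"),
         month_year = format(dob, "%Y-%m"),
         year = format(dob, "%Y"),
         suppressed = rep("", length(dob)))
}

#' Build quasi-identifier keys for every person
#'
#' Assembles, per person, the generalized date of birth, optionally the
#' gender, and the year-labelled sequence of cropped postal codes for the
#' selected trail years. No person is dropped at this stage. Key equality
#' is component-wise equality.
#'
#' @param registry A sentinel-encoded `registry`.
#' @param level A [generalization_level()].
#' @param trail A [trail_spec()] whose years lie inside the window.
#' @param sentinel_aware If `FALSE`, sentinel codes are blanked before
#'   cropping, emulating an adversary without birth/death knowledge.
#' @return Character vector of keys, one per person.
#' @export
build_quasi_identifiers <- function(registry, level, trail,
                                    sentinel_aware = TRUE) {
  stopifnot(inherits(level, "generalization_level"),
            inherits(trail, "trail_spec"))
  window <- registry_window(registry)
  if (!all(trail$years %in% window)) {
    stop("trail years must lie inside the registry window", call. = FALSE)
  }
  parts <- list(generalize_dob(registry$date_of_birth, level$dob_level))
  if (level$include_gender) parts <- c(parts, list(registry$gender))
  if (level$postal_chars > 0) {
    for (y in trail$years) {
      code <- registry[[paste0("pc_", y)]]
      if (!sentinel_aware) code[is_sentinel(code)] <- ""
      parts <- c(parts, list(paste0(y, ":", crop_postal(code, level$postal_chars))))
    }
  }
  do.call(paste, c(parts, sep = "|"))
}

#' Enumerate the generalization lattice
#'
#' Full cross product of DOB granularity, postal characters, gender flag
#' and trail length `1..window_years`, excluding the combinations with both
#' DOB and postal suppressed.
#'
#' @param window_years Number of years in the study window.
#' @return Data frame with columns `dob_level`, `postal_chars`,
#'   `gender_included`, `trail_length`.
#' @export
enumerate_lattice <- function(window_years) {
  stop_if_not_scalar_number(window_years, "window_years", positive = TRUE)
  grid <- expand.grid(dob_level = DOB_LEVELS,
                      postal_chars = 0:6,
                      gender_included = c(TRUE, FALSE),
                      trail_length = seq_len(window_years),
                      KEEP.OUT.ATTRS = FALSE,
                      stringsAsFactors = FALSE)
  grid <- grid[!(grid$dob_level == "suppressed" & grid$postal_chars == 0), ,
               drop = FALSE]
  rownames(grid) <- NULL
  grid
}
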