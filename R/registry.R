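# Registry container and CSV dialect.
#
# A registry is a data frame with columns person_id, gender ("M"/"F"),
# date_of_birth (Date), date_of_death (Date or NA), and one pc_<year>
# character column per window year (6-character postal code, sentinel, or
# "" for missing). The window is carried as an attribute.

#' Construct a registry from a data frame
#'
#' @param df Data frame with the registry columns.
#' @param window Integer vector of consecutive window years; inferred from
#'   the `pc_<year>` columns when `NULL`.
#' @return An object of class `registry`.
#' @export
as_registry <- function(df, window = NULL) {
  required <- c("person_id", "gender", "date_of_birth", "date_of_death")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols)) {
    stop("registry is missing mandatory columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  pc_cols <- grep("^pc_\\d{4}$", names(df), value = TRUE)
  inferred <- sort(as.integer(sub("^pc_", "", pc_cols)))
  if (is.null(window)) window <- inferred
  window <- as.integer(window)
  missing_years <- setdiff(window, inferred)
  if (length(missing_years)) {
    stop("registry is missing postal columns for window years: ",
         paste(missing_years, collapse = ", "), call. = FALSE)
  }
  rownames(df) <- NULL
  structure(df, window = window, class = c("registry", "data.frame"))
}

#' Window years of a registry
#' @param registry A `registry`.
#' @return Integer vector of window years.
#' @export
registry_window <- function(registry) {
  w <- attr(registry, "window")
  if (is.null(w)) {
    w <- sort(as.integer(sub("^pc_", "",
                             grep("^pc_\\d{4}$", names(registry), value = TRUE))))
  }
  w
}

pc_columns <- function(registry) paste0("pc_", registry_window(registry))

postal_matrix <- function(registry) {
  m <- as.matrix(registry[pc_columns(registry)])
  m[is.na(m)] <- ""
  mode(m) <- "character"
  m
}

set_postal_matrix <- function(registry, m) {
  registry[pc_columns(registry)] <- as.data.frame(m, stringsAsFactors = FALSE)
  registry
}

birth_years <- function(registry) {
  as.integer(format(registry$date_of_birth, "%Y"))
}

death_years <- function(registry) {
  as.integer(format(registry$date_of_death, "%Y"))
}

#' Read a registry CSV
#'
#' Parses the registry dialect (`person_id`, `gender`, ISO-8601
#' `date_of_birth`, `date_of_death` or empty, and `pc_<year>` columns).
#' Rows with unparseable dates or invalid gender are dropped from the
#' result and reported, with their row numbers, in the `"problems"`
#' attribute.
#'
#' @param path Path to the CSV file.
#' @param window Window years the file must cover; a missing `pc_<year>`
#'   column for any requested year is a hard error. Inferred when `NULL`.
#' @return A `registry`; `attr(x, "problems")` is a data frame of row-level
#'   parse failures (empty when the file is clean).
#' @export
read_registry <- function(path, window = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- utils::read.csv(path, colClasses = "character",
                         check.names = FALSE, na.strings = NULL)
  required <- c("person_id", "gender", "date_of_birth", "date_of_death")
  missing_cols <- setdiff(required, names(raw))
  if (length(missing_cols)) {
    stop("registry file is missing mandatory columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }

  dob <- as.Date(raw$date_of_birth, format = "%Y-%m-%d")
  dod_str <- raw$date_of_death
  dod <- as.Date(ifelse(dod_str == "", NA, dod_str), format = "%Y-%m-%d")

  problem_rows <- function(rows, column, issue) {
    data.frame(row = rows, column = rep(column, length(rows)),
               issue = rep(issue, length(rows)), stringsAsFactors = FALSE)
  }
  problems <- rbind(
    problem_rows(which(is.na(dob)), "date_of_birth", "unparseable date"),
    problem_rows(which(dod_str != "" & is.na(dod)), "date_of_death",
                 "unparseable date"),
    problem_rows(which(!raw$gender %in% c("M", "F")), "gender",
                 "gender not M/F")
  )

  raw$date_of_birth <- dob
  raw$date_of_death <- dod
  bad <- unique(problems$row)
  if (length(bad)) raw <- raw[-bad, , drop = FALSE]
  reg <- as_registry(raw, window)
  attr(reg, "problems") <- problems[order(problems$row), , drop = FALSE]
  reg
}

#' Write a registry CSV
#'
#' @param registry A `registry`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_registry <- function(registry, path) {
  out <- as.data.frame(registry)
  out$date_of_birth <- format(out$date_of_birth, "%Y-%m-%d")
  out$date_of_death <- ifelse(is.na(out$date_of_death), "",
                              format(out$date_of_death, "%Y-%m-%d"))
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Quality-control filter
#'
#' Applies the registry's two removal rules: (a) persons whose postal
#' fields are empty for every window year; (b) persons with a non-empty
#' postal code in a year strictly before their birth year or strictly
#' after their death year. Record order is preserved. Idempotent.
#'
#' @param registry A `registry` that has not been sentinel-encoded.
#' @return A list with elements `registry` (the survivors) and `report`
#'   (class `qc_report`: `n_input`, `n_removed_missing_all`,
#'   `n_removed_inconsistent`, `n_retained`, `removal_fraction`).
#' @export
qc_filter <- function(registry) {
  pcm <- postal_matrix(registry)
  if (any(is_sentinel(pcm))) {
    stop("qc_filter must run before sentinel encoding", call. = FALSE)
  }
  years <- registry_window(registry)
  n <- nrow(registry)
  by <- birth_years(registry)
  dy <- death_years(registry)
  dy[is.na(dy)] <- .Machine$integer.max

  nonempty <- pcm != ""
  all_missing <- rowSums(nonempty) == 0
  yr <- matrix(years, n, length(years), byrow = TRUE)
  out_of_life <- nonempty & (yr < by | yr > dy)
  inconsistent <- !all_missing & rowSums(out_of_life) > 0
  keep <- !all_missing & !inconsistent

  report <- structure(list(
    n_input = n,
    n_removed_missing_all = sum(all_missing),
    n_removed_inconsistent = sum(inconsistent),
    n_retained = sum(keep),
    removal_fraction = if (n > 0) (n - sum(keep)) / n else 0
  ), class = "qc_report")

  kept <- registry[keep, , drop = FALSE]
  rownames(kept) <- NULL
  list(registry = as_registry(kept, years), report = report)
}

#' @export
print.qc_report <- function(x, ...) {
  cat(sprintf(paste0("<qc_report> %d records: %d removed all-missing, ",
                     "%d removed inconsistent, %d retained (%.2f%% removed)\n"),
              x$n_input, x$n_removed_missing_all, x$n_removed_inconsistent,
              x$n_retained, 100 * x$removal_fraction))
  invisible(x)
}

#' Encode unborn/dead sentinel postal codes
#'
#' Replaces window years strictly before a person's birth year with
#' `"UUUUUU"` and years strictly after their death year with `"DDDDDD"`,
#' modelling an adversary who knows vital status. Real codes are never
#' altered. The registry must already have passed [qc_filter()]; an empty
#' in-life postal value is a contract violation and raises an error.
#'
#' @param registry A QC'd `registry`.
#' @return The sentinel-encoded `registry`.
#' @export
encode_sentinels <- function(registry) {
  pcm <- postal_matrix(registry)
  years <- registry_window(registry)
  n <- nrow(registry)
  by <- birth_years(registry)
  dy <- death_years(registry)
  dy[is.na(dy)] <- .Machine$integer.max
  yr <- matrix(years, n, length(years), byrow = TRUE)

  pcm[yr < by] <- SENTINEL_UNBORN
  pcm[yr > dy] <- SENTINEL_DEAD
  if (any(pcm == "")) {
    bad <- which(rowSums(pcm == "") > 0)
    stop("empty in-life postal value(s) after QC (e.g. record ", bad[1],
         "); registry violates the QC contract", call. = FALSE)
  }
  set_postal_matrix(registry, pcm)
}

#' @export
print.registry <- function(x, ...) {
  w <- registry_window(x)
  cat(sprintf("<registry> %d persons, window %d-%d (%d years)\n",
              nrow(x), min(w), max(w), length(w)))
  invisible(x)
}
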