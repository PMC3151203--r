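# Canadian-style postal geography for the synthetic registry.
#
# Codes are 6 characters, letter-digit alternating (LDLDLD), stored without
# the display space. The first three characters form the forward sortation
# area (FSA); codes are generated hierarchically under FSAs so prefix
# cropping always yields a consistent area hierarchy. Letters D, F, I, O, Q
# and U are never used (Canada Post convention), which also keeps real codes
# disjoint from the unborn/dead sentinel prefixes.

#' Sentinel postal codes
#'
#' Placeholder codes marking window years strictly before birth
#' (`"UUUUUU"`) or strictly after death (`"DDDDDD"`). Encoding these into a
#' trail models an adversary who knows a target's vital status.
#'
#' @format Character scalars.
#' @export
SENTINEL_UNBORN <- "UUUUUU"

#' @rdname SENTINEL_UNBORN
#' @export
SENTINEL_DEAD <- "DDDDDD"

postal_letters <- function() setdiff(LETTERS, c("D", "F", "I", "O", "Q", "U"))

is_sentinel <- function(code) code %in% c(SENTINEL_UNBORN, SENTINEL_DEAD)

#' Build a synthetic postal-code universe
#'
#' Generates `n_codes` unique 6-character postal codes grouped under FSAs,
#' with per-code population shares and urban/rural flags. Shares are drawn
#' log-normal so that, for a population of `n_codes * mean_cell_size`
#' persons, implied per-code cell sizes have approximately the requested
#' mean and a right-skewed spread (median below the mean). The default
#' skew reproduces 6-character cells with mean ~48 and median ~30 residents,
#' the calibration profile of a large Canadian city.
#'
#' @param n_codes Number of distinct postal codes (>= 1).
#' @param mean_cell_size Target mean residents per code (> 0).
#' @param seed Integer seed; the universe is deterministic given the seed.
#' @param median_cell_size Target median residents per code; together with
#'   `mean_cell_size` this fixes the log-normal spread. Must not exceed
#'   `mean_cell_size`.
#' @param urban_fraction Probability a code is flagged urban.
#' @return An object of class `postal_universe`: a data frame with columns
#'   `code`, `share`, `urban`, plus attributes `mean_cell_size` and `seed`.
#' @export
build_postal_universe <- function(n_codes, mean_cell_size = 48, seed = 1L,
                                  median_cell_size = 30,
                                  urban_fraction = 0.85) {
  stop_if_not_scalar_number(n_codes, "n_codes", positive = TRUE)
  stop_if_not_scalar_number(mean_cell_size, "mean_cell_size", positive = TRUE)
  stop_if_not_scalar_number(median_cell_size, "median_cell_size", positive = TRUE)
  if (median_cell_size > mean_cell_size) {
    stop("`median_cell_size` must not exceed `mean_cell_size`", call. = FALSE)
  }
  n_codes <- as.integer(n_codes)

  with_seed(seed, {
    codes <- generate_codes(n_codes)
    if (n_codes == 1) {
      share <- 1
    } else {
      sdlog <- sqrt(2 * log(mean_cell_size / median_cell_size))
      raw <- stats::rlnorm(n_codes, meanlog = log(median_cell_size), sdlog = sdlog)
      share <- raw / sum(raw)
    }
    urban <- stats::rbinom(n_codes, 1, urban_fraction) == 1

    universe <- data.frame(code = codes, share = share, urban = urban,
                           stringsAsFactors = FALSE)
    structure(universe,
              mean_cell_size = mean_cell_size,
              seed = seed,
              class = c("postal_universe", "data.frame"))
  })
}

# Hierarchical code generation: sample distinct FSAs (letter-digit-letter),
# then distinct local delivery units (digit-letter-digit) within each FSA.
generate_codes <- function(n_codes) {
  letters_ok <- postal_letters()
  n_l <- length(letters_ok)
  fsa_space <- n_l * 10 * n_l
  ldu_space <- 10 * n_l * 10

  ldu_per_fsa <- min(ldu_space, max(1L, 30L))
  n_fsa <- min(fsa_space, max(1L, ceiling(n_codes / ldu_per_fsa)))

  fsa_idx <- sample.int(fsa_space, n_fsa) - 1L
  fsa <- paste0(letters_ok[fsa_idx %/% (10 * n_l) + 1L],
                (fsa_idx %/% n_l) %% 10,
                letters_ok[fsa_idx %% n_l + 1L])

  # spread codes round-robin across FSAs
  per_fsa <- tabulate(rep_len(seq_len(n_fsa), n_codes), nbins = n_fsa)
  if (any(per_fsa > ldu_space)) {
    stop("`n_codes` too large for the postal code space", call. = FALSE)
  }
  codes <- unlist(lapply(seq_len(n_fsa), function(i) {
    if (per_fsa[i] == 0L) return(character(0))
    ldu_idx <- sample.int(ldu_space, per_fsa[i]) - 1L
    paste0(fsa[i],
           ldu_idx %/% (n_l * 10),
           letters_ok[(ldu_idx %/% 10) %% n_l + 1L],
           ldu_idx %% 10)
  }), use.names = FALSE)
  codes
}

#' @export
print.postal_universe <- function(x, ...) {
  cat(sprintf("<postal_universe> %d codes, %d FSAs, %.0f%% urban\n",
              nrow(x), length(unique(substr(x$code, 1, 3))),
              100 * mean(x$urban)))
  invisible(x)
}
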