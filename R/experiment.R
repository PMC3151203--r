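# Study-point experiment loop.
#
# A study point is one generalization level plus a trail length k. Its
# uniqueness is the average over random k-subsets of window years,
# iterated until the cumulative mean stabilizes (change below delta for a
# run of consecutive iterations) or an iteration cap is reached.

#' Stopping rule for the iterative study-point average
#'
#' The cumulative mean is deemed stable once its change between successive
#' iterations stays below `delta` for `window` consecutive iterations
#' (counting from the first delta available), with at least
#' `min_iterations` and at most `max_iterations` iterations. The
#' `"lag"` criterion instead compares the mean to its value `window`
#' iterations earlier.
#'
#' @param delta Change threshold on the running average.
#' @param window Number of consecutive small changes required.
#' @param max_iterations,min_iterations Iteration bounds.
#' @param criterion `"consecutive"` (default) or `"lag"`.
#' @return An object of class `stopping_rule`.
#' @export
stopping_rule <- function(delta = 1e-4, window = 10L,
                          max_iterations = 1000L, min_iterations = 10L,
                          criterion = c("consecutive", "lag")) {
  stop_if_not_scalar_number(delta, "delta", positive = TRUE)
  if (window < 1) stop("`window` must be >= 1", call. = FALSE)
  if (min_iterations > max_iterations) {
    stop("`min_iterations` must not exceed `max_iterations`", call. = FALSE)
  }
  structure(list(delta = delta, window = as.integer(window),
                 max_iterations = as.integer(max_iterations),
                 min_iterations = as.integer(min_iterations),
                 criterion = match.arg(criterion)),
            class = "stopping_rule")
}

#' Draw a random trail-year subset
#'
#' Uniform draw of a `k`-subset of the window years, without replacement
#' within a draw. Uses the current RNG state.
#'
#' @param window_years Vector of candidate calendar years.
#' @param k Trail length, `1 <= k <= length(window_years)`.
#' @return A [trail_spec()].
#' @export
sample_trail_years <- function(window_years, k) {
  window_years <- as.integer(window_years)
  if (k < 1 || k > length(window_years)) {
    stop("`k` must lie in 1..length(window_years)", call. = FALSE)
  }
  trail_spec(window_years[sample.int(length(window_years), k)])
}

#' Run one study point
#'
#' Repeatedly draws a trail of `k` window years, builds quasi-identifier
#' keys at `level`, computes uniqueness (exact, or Zayatz when the registry
#' is a sample), and updates the running mean until the stopping rule
#' fires. When only one `k`-subset exists (`k` equals the window length) a
#' single iteration is performed.
#'
#' @param registry A QC'd, sentinel-encoded `registry`.
#' @param level A [generalization_level()].
#' @param k Trail length.
#' @param rule A [stopping_rule()].
#' @param method `"exact"` or `"zayatz"`.
#' @param design A [sampling_design()]; required for `method = "zayatz"`.
#' @param seed Optional integer seed (RNG state restored afterwards).
#' @param stratum Label recorded in the result.
#' @param sentinel_aware Passed to [build_quasi_identifiers()].
#' @return An `estimate_result`: list with `level`, `k`, `stratum`,
#'   `method`, `mean` (final average uniqueness), `iterations`, `values`
#'   (per-iteration uniqueness), `means` (running mean trace), `seed`.
#' @export
run_study_point <- function(registry, level, k, rule = stopping_rule(),
                            method = c("exact", "zayatz"), design = NULL,
                            seed = NULL, stratum = "all",
                            sentinel_aware = TRUE) {
  method <- match.arg(method)
  if (!nrow(registry)) stop("empty registry", call. = FALSE)
  if (method == "zayatz" && is.null(design)) {
    stop("`design` is required for the Zayatz method", call. = FALSE)
  }
  window <- registry_window(registry)
  if (k < 1 || k > length(window)) {
    stop("`k` must lie in 1..window length", call. = FALSE)
  }

  with_seed(seed, {
    single <- k == length(window)
    max_it <- if (single) 1L else rule$max_iterations
    values <- numeric(0)
    means <- numeric(0)
    consec <- 0L
    i <- 0L
    repeat {
      i <- i + 1L
      trail <- sample_trail_years(window, k)
      keys <- build_quasi_identifiers(registry, level, trail,
                                      sentinel_aware = sentinel_aware)
      spec <- frequency_spectrum(keys)
      u <- if (method == "exact") {
        exact_uniqueness(spec)$value
      } else {
        zayatz_estimate(spec, design)$value
      }
      values[i] <- u
      means[i] <- if (i == 1L) u else means[i - 1L] + (u - means[i - 1L]) / i
      if (i >= max_it) break
      stable <- if (rule$criterion == "consecutive") {
        if (i >= 2L) {
          consec <- if (abs(means[i] - means[i - 1L]) < rule$delta)
            consec + 1L else 0L
        }
        # all deltas available so far (up to `window` of them) are small
        consec >= min(rule$window, i - 1L) && consec > 0L
      } else {
        i > rule$window &&
          abs(means[i] - means[i - rule$window]) < rule$delta
      }
      if (i >= rule$min_iterations && stable) break
    }
    structure(list(level = level, k = as.integer(k), stratum = stratum,
                   method = method, mean = means[i],
                   iterations = i, values = values, means = means,
                   seed = seed),
              class = "estimate_result")
  })
}

#' @export
print.estimate_result <- function(x, ...) {
  cat(sprintf(paste0("<estimate_result> %s/%s, dob=%s, postal=%d, gender=%s,",
                     " k=%d: mean uniqueness %.4f over %d iterations\n"),
              x$stratum, x$method, x$level$dob_level, x$level$postal_chars,
              x$level$include_gender, x$k, x$mean, x$iterations))
  invisible(x)
}

#' @export
as.data.frame.estimate_result <- function(x, ...) {
  data.frame(stratum = x$stratum, trail_length = x$k,
             dob_level = x$level$dob_level,
             postal_chars = x$level$postal_chars,
             gender_included = x$level$include_gender,
             method = x$method, mean_uniqueness = x$mean,
             n_iterations = x$iterations, stringsAsFactors = FALSE)
}

#' Split a registry into youth and adults for a trail
#'
#' A person is a youth if their calendar-year age (`year - birth year`) is
#' below 20 in every selected trail year; everyone else is an adult. The
#' split is exhaustive and disjoint.
#'
#' @param registry A `registry`.
#' @param trail A [trail_spec()].
#' @return List with `registry` elements `youth` and `adult`.
#' @export
stratify_youth_adult <- function(registry, trail) {
  stopifnot(inherits(trail, "trail_spec"))
  window <- registry_window(registry)
  age_last <- max(trail$years) - birth_years(registry)
  youth <- age_last < 20
  list(youth = as_registry(registry[youth, , drop = FALSE], window),
       adult = as_registry(registry[!youth, , drop = FALSE], window))
}

#' Extreme-case sensitivity bounds for QC removals
#'
#' If a fraction `r` of records was removed by quality control, the
#' observed uniqueness `u` on retained records brackets the uniqueness
#' that would have been observed had the removed records been corrected
#' and retained: at most `(1-r)*u + r` (every removed record unique) and
#' at least `(1-r)*u` (no removed record unique, none colliding with a
#' retained unique).
#'
#' @param u Observed uniqueness on retained records, in `[0, 1]`.
#' @param r Removal fraction, in `[0, 1]` (default 0.06).
#' @return List with elements `u_min` and `u_max`.
#' @export
sensitivity_bounds <- function(u, r = 0.06) {
  if (any(u < 0 | u > 1) || any(r < 0 | r > 1)) {
    stop("`u` and `r` must lie in [0, 1]", call. = FALSE)
  }
  list(u_min = (1 - r) * u, u_max = (1 - r) * u + r)
}

#' Disclosure-risk policy thresholds
#'
#' @param strict Threshold for untrusted recipients (default 5%).
#' @param relaxed Threshold for trusted recipients (default 20%).
#' @return An object of class `policy_thresholds`.
#' @export
policy_thresholds <- function(strict = 0.05, relaxed = 0.20) {
  if (!(0 < strict && strict < relaxed && relaxed < 1)) {
    stop("need 0 < strict < relaxed < 1", call. = FALSE)
  }
  structure(list(strict = strict, relaxed = relaxed),
            class = "policy_thresholds")
}

#' Build a disclosure policy table
#'
#' Flags each study-point result as acceptable under the strict and
#' relaxed uniqueness thresholds (a mean exactly at a threshold is
#' acceptable). Strict acceptability implies relaxed acceptability.
#'
#' @param results A list of `estimate_result` objects, or a data frame
#'   with at least a `mean_uniqueness` column.
#' @param thresholds A [policy_thresholds()].
#' @return Data frame of study points with logical columns
#'   `acceptable_strict` and `acceptable_relaxed`.
#' @export
policy_table <- function(results, thresholds = policy_thresholds()) {
  stopifnot(inherits(thresholds, "policy_thresholds"))
  if (is.data.frame(results)) {
    df <- results
  } else {
    df <- do.call(rbind, lapply(results, as.data.frame))
  }
  if (!"mean_uniqueness" %in% names(df)) {
    stop("`results` must provide a mean_uniqueness column", call. = FALSE)
  }
  df$acceptable_strict <- df$mean_uniqueness <= thresholds$strict
  df$acceptable_relaxed <- df$mean_uniqueness <= thresholds$relaxed
  df
}
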