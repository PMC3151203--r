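# Component models of the synthetic registry generator.

#' Residential mobility model
#'
#' Categorical distribution of the number of address changes a person makes
#' across the study window. The default marginal is 48/21/17/8/6% for
#' 0/1/2/3/4+ moves. The open-ended "4+" category is expanded into a
#' geometric tail (decay `tail_decay`) capped at `window years - 1` when the
#' model is applied to a window.
#'
#' @param move_probs Named numeric vector with names `"0".."3"` and `"4+"`;
#'   must sum to 1.
#' @param tail_decay Geometric decay of the 4+ tail, in (0, 1).
#' @return An object of class `mobility_model`.
#' @export
mobility_model <- function(move_probs = c("0" = 0.48, "1" = 0.21, "2" = 0.17,
                                          "3" = 0.08, "4+" = 0.06),
                           tail_decay = 0.5) {
  if (!setequal(names(move_probs), c("0", "1", "2", "3", "4+"))) {
    stop("`move_probs` must be named '0','1','2','3','4+'", call. = FALSE)
  }
  if (any(move_probs < 0) || abs(sum(move_probs) - 1) > 1e-9) {
    stop("`move_probs` must be non-negative and sum to 1 (tol 1e-9)",
         call. = FALSE)
  }
  if (tail_decay <= 0 || tail_decay >= 1) {
    stop("`tail_decay` must be in (0, 1)", call. = FALSE)
  }
  structure(list(move_probs = move_probs[c("0", "1", "2", "3", "4+")],
                 tail_decay = tail_decay),
            class = "mobility_model")
}

#' Expand a mobility model to a full move-count distribution
#'
#' Distributes the 4+ mass geometrically over counts `4..max_moves`.
#'
#' @param model A [mobility_model()].
#' @param max_moves Cap on move counts (window years - 1).
#' @return Numeric probability vector over `0:max_moves` (names are counts).
#' @export
expand_move_distribution <- function(model, max_moves) {
  stopifnot(inherits(model, "mobility_model"))
  max_moves <- as.integer(max_moves)
  if (max_moves < 1) stop("`max_moves` must be >= 1", call. = FALSE)
  p <- unname(model$move_probs)
  if (max_moves <= 3) {
    # short windows: fold excess mass into the cap
    out <- p[seq_len(max_moves + 1)]
    out[max_moves + 1] <- 1 - sum(out[seq_len(max_moves)])
  } else {
    tail_counts <- 4:max_moves
    w <- model$tail_decay^(tail_counts - 4)
    out <- c(p[1:4], p[5] * w / sum(w))
  }
  names(out) <- 0:max_moves
  out
}

#' Demography model
#'
#' Age structure, gender ratio and vital events for the synthetic
#' population. Ages at the window start follow a piecewise-uniform pyramid
#' over integer ages; a fraction of persons is instead born inside the
#' window (uniformly over window years); deaths follow a Gompertz annual
#' hazard `rate0 * exp(growth * age)`.
#'
#' @param age_band_breaks Increasing integer breaks; band `i` covers ages
#'   `breaks[i] .. breaks[i+1] - 1`.
#' @param age_band_weights Probability of each band (sums to 1).
#' @param female_share Probability of gender `"F"`.
#' @param birth_fraction Fraction of persons born inside the window.
#' @param mortality_rate0,mortality_growth Gompertz hazard parameters; the
#'   annual death probability at age `a` is `min(1, rate0 * exp(growth*a))`.
#' @return An object of class `demography_model`.
#' @export
demography_model <- function(age_band_breaks = c(0L, 20L, 45L, 65L, 91L),
                             age_band_weights = c(0.32, 0.36, 0.19, 0.13),
                             female_share = 0.51,
                             birth_fraction = 0.10,
                             mortality_rate0 = 5e-5,
                             mortality_growth = 0.09) {
  if (length(age_band_weights) != length(age_band_breaks) - 1) {
    stop("`age_band_weights` must have one entry per band", call. = FALSE)
  }
  if (any(diff(age_band_breaks) <= 0)) {
    stop("`age_band_breaks` must be strictly increasing", call. = FALSE)
  }
  probs <- c(age_band_weights, female_share, birth_fraction)
  if (any(probs < 0 | probs > 1) || abs(sum(age_band_weights) - 1) > 1e-9) {
    stop("demography probabilities must lie in [0,1] and band weights sum to 1",
         call. = FALSE)
  }
  if (mortality_rate0 < 0 || mortality_growth < 0) {
    stop("mortality parameters must be non-negative", call. = FALSE)
  }
  structure(list(age_band_breaks = as.integer(age_band_breaks),
                 age_band_weights = age_band_weights,
                 female_share = female_share,
                 birth_fraction = birth_fraction,
                 mortality_rate0 = mortality_rate0,
                 mortality_growth = mortality_growth),
            class = "demography_model")
}

annual_death_prob <- function(model, age) {
  pmin(1, model$mortality_rate0 * exp(model$mortality_growth * pmax(0, age)))
}

#' Data-quality corruption model
#'
#' Per-person corruption emulating registry data-entry errors: with
#' probability `p_missing_all` every postal field is blanked; with
#' probability `p_inconsistent` a postal code is injected into a year
#' strictly before birth or strictly after death. The two flags are
#' mutually exclusive per person.
#'
#' @param p_missing_all,p_inconsistent Probabilities; their sum must be <= 1.
#' @return An object of class `corruption_model`.
#' @export
corruption_model <- function(p_missing_all = 0.01, p_inconsistent = 0.05) {
  if (p_missing_all < 0 || p_inconsistent < 0 ||
      p_missing_all + p_inconsistent > 1) {
    stop("corruption probabilities must be >= 0 and sum to <= 1",
         call. = FALSE)
  }
  structure(list(p_missing_all = p_missing_all,
                 p_inconsistent = p_inconsistent),
            class = "corruption_model")
}

#' Synthetic registry configuration
#'
#' Bundles the generator's components and the study window. If `universe`
#' is `NULL`, a universe sized for ~48 residents per code is built from the
#' same seed.
#'
#' @param n_persons Number of persons to generate (>= 1).
#' @param first_year,last_year Calendar window (inclusive); defaults to the
#'   11-year window 1996-2006.
#' @param universe A [build_postal_universe()] result, or `NULL`.
#' @param mobility A [mobility_model()].
#' @param demography A [demography_model()].
#' @param corruption A [corruption_model()] (applied separately via
#'   [apply_corruption()]).
#' @param seed Integer seed making generation deterministic.
#' @return An object of class `synth_config`.
#' @export
synth_config <- function(n_persons,
                         first_year = 1996L, last_year = 2006L,
                         universe = NULL,
                         mobility = mobility_model(),
                         demography = demography_model(),
                         corruption = corruption_model(),
                         seed = 1L) {
  stop_if_not_scalar_number(n_persons, "n_persons", positive = TRUE)
  if (last_year < first_year) {
    stop("`last_year` must be >= `first_year`", call. = FALSE)
  }
  stopifnot(inherits(mobility, "mobility_model"),
            inherits(demography, "demography_model"),
            inherits(corruption, "corruption_model"))
  if (is.null(universe)) {
    universe <- build_postal_universe(max(1L, round(n_persons / 48)),
                                      seed = seed)
  }
  stopifnot(inherits(universe, "postal_universe"))
  structure(list(n_persons = as.integer(n_persons),
                 first_year = as.integer(first_year),
                 last_year = as.integer(last_year),
                 universe = universe,
                 mobility = mobility,
                 demography = demography,
                 corruption = corruption,
                 seed = as.integer(seed)),
            class = "synth_config")
}
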