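# Uniqueness measures.
#
# The frequency spectrum c_j (number of equivalence classes with exactly j
# records) is the sufficient statistic for every estimator here. Exact
# population uniqueness is c_1 / T. When only a simple random sample is
# available, population uniqueness is estimated with the Zayatz
# sample-uniques estimator: the probability that a sample-unique record is
# population-unique is computed by Bayes' rule with a hypergeometric
# subsampling kernel and the sample spectrum as plug-in prior over
# population class sizes.

#' Frequency spectrum of equivalence classes
#'
#' @param keys Character vector of quasi-identifier keys (one per record).
#' @return A `frequency_spectrum`: named integer vector mapping class size
#'   `j` to the number of classes `c_j`, with attributes `n_records`
#'   (`T = sum j * c_j`) and `n_classes` (`C = sum c_j`).
#' @export
frequency_spectrum <- function(keys) {
  if (!length(keys)) {
    stop("cannot build a frequency spectrum from zero records", call. = FALSE)
  }
  class_sizes <- tabulate(match(keys, unique(keys)))
  tab <- tabulate(class_sizes)
  sizes <- which(tab > 0)
  counts <- tab[sizes]
  new_frequency_spectrum(sizes, counts)
}

#' Construct a frequency spectrum from (size, count) pairs
#'
#' @param sizes Integer class sizes `j`.
#' @param counts Integer class counts `c_j` (same length).
#' @return A `frequency_spectrum`.
#' @export
new_frequency_spectrum <- function(sizes, counts) {
  sizes <- as.integer(sizes)
  counts <- as.integer(counts)
  stopifnot(length(sizes) == length(counts), !anyNA(sizes), !anyNA(counts))
  if (any(sizes < 1) || any(counts < 0) || anyDuplicated(sizes)) {
    stop("class sizes must be distinct positive integers with counts >= 0",
         call. = FALSE)
  }
  o <- order(sizes)
  x <- counts[o]
  names(x) <- sizes[o]
  structure(x,
            n_records = sum(as.numeric(sizes) * counts),
            n_classes = sum(counts),
            class = "frequency_spectrum")
}

spectrum_sizes <- function(spectrum) as.integer(names(spectrum))

#' @export
print.frequency_spectrum <- function(x, ...) {
  cat(sprintf("<frequency_spectrum> %d classes, %.0f records\n",
              attr(x, "n_classes"), attr(x, "n_records")))
  print(stats::setNames(as.integer(x), names(x)))
  invisible(x)
}

#' Exact population uniqueness
#'
#' The proportion of records that are population-unique: `u = c_1 / T`.
#'
#' @param spectrum A [frequency_spectrum()].
#' @return A `uniqueness_estimate` with fields `value`, `method`
#'   (`"exact"`), `spectrum`.
#' @export
exact_uniqueness <- function(spectrum) {
  stopifnot(inherits(spectrum, "frequency_spectrum"))
  n_rec <- attr(spectrum, "n_records")
  if (n_rec == 0) stop("uniqueness is undefined for zero records", call. = FALSE)
  c1 <- if ("1" %in% names(spectrum)) spectrum[["1"]] else 0L
  structure(list(value = c1 / n_rec, method = "exact",
                 spectrum = spectrum, design = NULL),
            class = "uniqueness_estimate")
}

#' Sampling design for the Zayatz estimator
#'
#' @param N Population size.
#' @param n Sample size, `1 <= n <= N`.
#' @return A `sampling_design` with fields `N`, `n` and sampling fraction
#'   `pi = n / N`.
#' @export
sampling_design <- function(N, n) {
  stop_if_not_scalar_number(N, "N", positive = TRUE)
  stop_if_not_scalar_number(n, "n", positive = TRUE)
  if (n > N) stop("`n` must not exceed `N`", call. = FALSE)
  structure(list(N = N, n = n, pi = n / N), class = "sampling_design")
}

#' Probability a population class of size j yields exactly one sampled record
#'
#' Hypergeometric: `j * choose(N-j, n-1) / choose(N, n)`, evaluated in log
#' space. The `"binomial"` kernel uses the large-N approximation
#' `j * pi * (1-pi)^(j-1)`.
#'
#' @param j Population class size(s), `1 <= j <= N`.
#' @param design A [sampling_design()].
#' @param kernel `"hypergeometric"` (exact, default) or `"binomial"`.
#' @return Probability vector, same length as `j`.
#' @export
p_sample_unique_given_pop_size <- function(j, design,
                                           kernel = c("hypergeometric",
                                                      "binomial")) {
  stopifnot(inherits(design, "sampling_design"))
  kernel <- match.arg(kernel)
  j <- as.numeric(j)
  if (any(j < 1) || any(j > design$N)) {
    stop("`j` must lie in 1..N", call. = FALSE)
  }
  if (kernel == "binomial") {
    return(j * design$pi * (1 - design$pi)^(j - 1))
  }
  N <- design$N
  n <- design$n
  out <- numeric(length(j))
  feasible <- (N - j) >= (n - 1)
  jf <- j[feasible]
  out[feasible] <- exp(log(jf) + lchoose(N - jf, n - 1) - lchoose(N, n))
  out
}

#' Zayatz estimate of population uniqueness from a sample
#'
#' With sample spectrum `c_j` (`C = sum c_j` classes), the probability that
#' a sample unique is a population unique is
#' `P = p(1) * (c_1/C) / sum_j p(j) * (c_j/C)` where `p(j)` is
#' [p_sample_unique_given_pop_size()]. The estimated number of population
#' uniques is `c_1 * P / pi`, and the returned uniqueness is that number
#' over `N`, clamped to `[0, 1]`. At `pi = 1` the estimate reduces exactly
#' to the sample's exact uniqueness.
#'
#' @param sample_spectrum [frequency_spectrum()] of the sample (assumed a
#'   simple random sample of the population).
#' @param design A [sampling_design()].
#' @param kernel Subsampling kernel, see
#'   [p_sample_unique_given_pop_size()].
#' @return A `uniqueness_estimate` with fields `value`, `method`
#'   (`"zayatz"`), `spectrum`, `design`.
#' @export
zayatz_estimate <- function(sample_spectrum, design,
                            kernel = c("hypergeometric", "binomial")) {
  stopifnot(inherits(sample_spectrum, "frequency_spectrum"),
            inherits(design, "sampling_design"))
  kernel <- match.arg(kernel)
  sizes <- spectrum_sizes(sample_spectrum)
  counts <- as.numeric(sample_spectrum)
  c1 <- if (1 %in% sizes) counts[sizes == 1] else 0

  value <- 0
  if (c1 > 0) {
    n_classes <- sum(counts)
    p <- p_sample_unique_given_pop_size(sizes, design, kernel)
    p1 <- p_sample_unique_given_pop_size(1, design, kernel)
    p_pop_unique <- (p1 * c1 / n_classes) / sum(p * counts / n_classes)
    n1_hat <- c1 * p_pop_unique / design$pi
    value <- min(1, max(0, n1_hat / design$N))
  }
  structure(list(value = value, method = "zayatz",
                 spectrum = sample_spectrum, design = design),
            class = "uniqueness_estimate")
}

#' @export
print.uniqueness_estimate <- function(x, ...) {
  cat(sprintf("<uniqueness_estimate> %s: %.4f (%.2f%%)\n",
              x$method, x$value, 100 * x$value))
  invisible(x)
}
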