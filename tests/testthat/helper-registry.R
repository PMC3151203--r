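# Fixture builders shared across the suite. Everything is generated in
# code; no stored data.

default_window <- 1996:2006

# A hand-built registry for QC/sentinel edge cases. `trails` is a named
# list person_id -> character vector over `years` ("" = missing).
manual_registry <- function(trails, births, deaths = NULL, genders = NULL,
                            years = default_window) {
  n <- length(trails)
  deaths <- deaths %||% rep(NA_character_, n)
  genders <- genders %||% rep("F", n)
  df <- data.frame(person_id = names(trails) %||% sprintf("P%03d", seq_len(n)),
                   gender = genders,
                   date_of_birth = as.Date(births),
                   date_of_death = as.Date(deaths),
                   stringsAsFactors = FALSE)
  pcm <- do.call(rbind, trails)
  colnames(pcm) <- paste0("pc_", years)
  as_registry(cbind(df, as.data.frame(pcm, stringsAsFactors = FALSE)), years)
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# Small generated registry, QC'd and sentinel-encoded.
small_encoded_registry <- function(n = 500, seed = 1L, ...) {
  cfg <- synth_config(n, seed = seed, ...)
  encode_sentinels(qc_filter(generate_population(cfg))$registry)
}

# O(n^2) pairwise oracle for the frequency spectrum.
brute_force_spectrum <- function(keys) {
  n <- length(keys)
  class_size <- vapply(seq_len(n), function(i) sum(keys == keys[i]),
                       integer(1))
  seen <- character(0)
  sizes <- integer(0)
  for (i in seq_len(n)) {
    if (!(keys[i] %in% seen)) {
      seen <- c(seen, keys[i])
      sizes <- c(sizes, class_size[i])
    }
  }
  tab <- table(sizes)
  new_frequency_spectrum(as.integer(names(tab)), as.integer(tab))
}

# Population with exactly controlled uniqueness: round(u*N) singleton
# classes, the rest in classes of `class_size`. Returns class ids.
controlled_population <- function(N, u_true, class_size = 100L) {
  n1 <- round(u_true * N)
  rest <- N - n1
  k <- rest %/% class_size
  rem <- rest - k * class_size
  sizes <- c(rep(class_size, k), if (rem > 1) rem)
  if (rem == 1) n1 <- n1 + 1
  rep.int(seq_len(n1 + length(sizes)), c(rep(1L, n1), sizes))
}

# Sample spectrum of an SRS of n from a population of class ids.
sample_spectrum <- function(pop, n) {
  samp <- sample(pop, n)
  cls <- tabulate(samp)
  cls <- cls[cls > 0]
  tab <- table(cls)
  new_frequency_spectrum(as.integer(names(tab)), as.integer(tab))
}

local_csv <- function() tempfile(fileext = ".csv")
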