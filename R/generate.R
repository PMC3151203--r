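# Synthetic population-registry generator.
#
# Emulates an annual-snapshot population registry: each person has a
# gender, a date of birth, possibly a date of death inside the window, and
# a postal code for every window year between birth and death (residence
# at the beginning of each year; within-year moves are not modelled).
# Address-change counts follow the configured move-count marginal; change
# years are placed uniformly at random among a person's in-life window
# years.

#' Generate a synthetic registry
#'
#' Deterministic for a fixed configuration (including its seed). The number
#' of address changes per person is drawn i.i.d. from the mobility model's
#' move-count distribution; because persons born or dying inside the window
#' cannot host arbitrarily many changes, infeasible draws are swapped with
#' feasible low-count draws of persons alive for the whole window, so the
#' population-level multiset of move counts equals the i.i.d. draw and the
#' realized marginal stays calibrated to the configured one.
#'
#' @param config A [synth_config()].
#' @return A `registry` with `config$n_persons` rows. Postal fields outside
#'   a person's lifetime are empty (`""`); see [encode_sentinels()].
#' @export
generate_population <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  with_seed(config$seed, {
    n <- config$n_persons
    years <- config$first_year:config$last_year
    W <- length(years)
    dem <- config$demography
    uni <- config$universe
    n_codes <- nrow(uni)

    gender <- ifelse(stats::runif(n) < dem$female_share, "F", "M")

    ## birth dates: window births vs pre-window age pyramid
    in_window <- stats::runif(n) < dem$birth_fraction
    birth_year <- integer(n)
    n_in <- sum(in_window)
    if (n_in) {
      birth_year[in_window] <- years[sample.int(W, n_in, replace = TRUE)]
    }
    n0 <- n - n_in
    if (n0) {
      band <- sample.int(length(dem$age_band_weights), n0, replace = TRUE,
                         prob = dem$age_band_weights)
      lo <- dem$age_band_breaks[band]
      hi <- dem$age_band_breaks[band + 1L] - 1L
      age0 <- lo + floor(stats::runif(n0) * (hi - lo + 1L))
      birth_year[!in_window] <- config$first_year - 1L - as.integer(age0)
    }
    bdoy <- 1L + as.integer(floor(stats::runif(n) * days_in_year(birth_year)))
    dob <- as.Date(paste0(birth_year, "-01-01")) + (bdoy - 1)

    ## deaths: annual Gompertz hazard on attained age
    death_year <- rep(NA_integer_, n)
    for (y in years) {
      alive <- is.na(death_year) & birth_year <= y
      idx <- which(alive)
      if (!length(idx)) next
      q <- annual_death_prob(dem, y - birth_year[idx])
      dies <- stats::runif(length(idx)) < q
      death_year[idx[dies]] <- y
    }
    has_d <- !is.na(death_year)
    dod <- as.Date(rep(NA_character_, n))
    if (any(has_d)) {
      dyv <- death_year[has_d]
      lo_doy <- ifelse(dyv == birth_year[has_d], bdoy[has_d], 1L)
      dd <- days_in_year(dyv)
      ddoy <- lo_doy + floor(stats::runif(sum(has_d)) * (dd - lo_doy + 1))
      dod[has_d] <- as.Date(paste0(dyv, "-01-01")) + (ddoy - 1)
    }

    ## in-life span within the window (snapshot at beginning of year:
    ## the birth year carries a real code, the death year the last one)
    si <- pmax(birth_year, config$first_year) - config$first_year + 1L
    ey <- ifelse(has_d, pmin(death_year, config$last_year), config$last_year)
    ei <- ey - config$first_year + 1L
    capacity <- ei - si  # available change slots

    ## move counts: i.i.d. draw, then capacity-respecting swap
    if (W > 1) {
      dist <- expand_move_distribution(config$mobility, W - 1L)
      m <- sample.int(W, n, replace = TRUE, prob = dist) - 1L
      m <- assign_feasible_moves(m, capacity, dist)
    } else {
      m <- integer(n)
    }

    ## change years: uniform without replacement among in-life slots
    movers <- which(m > 0L)
    if (length(movers)) {
      ch <- mapply(function(s, cap, mm) s + sample.int(cap, mm),
                   si[movers], capacity[movers], m[movers], SIMPLIFY = FALSE)
      mv_person <- rep(movers, m[movers])
      mv_yearidx <- unlist(ch, use.names = FALSE)
    } else {
      mv_person <- integer(0)
      mv_yearidx <- integer(0)
    }

    ## trail: start code at first in-life year, carry forward, movers redraw
    pcm <- matrix("", n, W)
    start <- sample.int(n_codes, n, replace = TRUE, prob = uni$share)
    pcm[cbind(seq_len(n), si)] <- uni$code[start]
    if (W > 1) {
      mv_by_year <- split(mv_person, factor(mv_yearidx, levels = seq_len(W)))
      for (t in 2:W) {
        carry <- which(si < t & ei >= t)
        pcm[carry, t] <- pcm[carry, t - 1L]
        mt <- mv_by_year[[t]]
        if (length(mt) && n_codes > 1) {
          cur <- pcm[mt, t]
          dest <- sample.int(n_codes, length(mt), replace = TRUE,
                             prob = uni$share)
          bad <- which(uni$code[dest] == cur)
          while (length(bad)) {
            dest[bad] <- sample.int(n_codes, length(bad), replace = TRUE,
                                    prob = uni$share)
            bad <- bad[uni$code[dest[bad]] == cur[bad]]
          }
          pcm[mt, t] <- uni$code[dest]
        }
      }
    }

    reg <- data.frame(person_id = sprintf("P%07d", seq_len(n)),
                      gender = gender,
                      date_of_birth = dob,
                      date_of_death = dod,
                      stringsAsFactors = FALSE)
    pcdf <- as.data.frame(pcm, stringsAsFactors = FALSE)
    names(pcdf) <- paste0("pc_", years)
    as_registry(cbind(reg, pcdf), years)
  })
}

# Swap infeasible move-count draws (m > capacity) with feasible low-count
# draws held by full-capacity persons; preserves the multiset of counts.
# If no full-capacity donor exists (degenerate configs) the draw is
# replaced by one from the capacity-truncated distribution.
assign_feasible_moves <- function(m, capacity, dist) {
  viol <- which(m > capacity)
  if (!length(viol)) return(m)
  max_cap <- max(capacity)
  donors <- which(capacity == max_cap)
  buckets <- split(donors, factor(m[donors], levels = seq_along(dist) - 1L))
  bsize <- lengths(buckets)
  bval <- as.integer(names(buckets))
  for (i in viol) {
    ok <- which(bval <= capacity[i] & bsize > 0)
    if (!length(ok) || max_cap < m[i]) {
      k <- capacity[i] + 1L
      m[i] <- if (k == 1L) 0L else
        sample.int(k, 1L, prob = dist[seq_len(k)]) - 1L
      next
    }
    b <- if (length(ok) == 1L) ok else sample(ok, 1L, prob = bsize[ok])
    pos <- if (bsize[b] == 1L) 1L else sample.int(bsize[b], 1L)
    j <- buckets[[b]][pos]
    buckets[[b]][pos] <- buckets[[b]][bsize[b]]
    bsize[b] <- bsize[b] - 1L
    mj <- m[j]
    m[j] <- m[i]
    m[i] <- mj
    nb <- m[j] + 1L
    bsize[nb] <- bsize[nb] + 1L
    if (bsize[nb] > length(buckets[[nb]])) {
      buckets[[nb]] <- c(buckets[[nb]], j)
    } else {
      buckets[[nb]][bsize[nb]] <- j
    }
  }
  m
}

#' Apply data-quality corruption to a registry
#'
#' Independently per person: with probability `p_missing_all` every postal
#' field is blanked; with probability `p_inconsistent` a postal code (the
#' person's own first code) is injected into a window year strictly before
#' birth or strictly after death. Inconsistency can only be applied to
#' persons having such out-of-life years; target persons are re-drawn among
#' the eligible. The flags are mutually exclusive per person.
#'
#' @param registry A `registry` that has not been sentinel-encoded.
#' @param corruption A [corruption_model()].
#' @param seed Integer seed.
#' @return The corrupted `registry`.
#' @export
apply_corruption <- function(registry, corruption = corruption_model(),
                             seed = 1L) {
  stopifnot(inherits(corruption, "corruption_model"))
  pcm <- postal_matrix(registry)
  if (any(is_sentinel(pcm))) {
    stop("apply_corruption must run before sentinel encoding", call. = FALSE)
  }
  years <- registry_window(registry)
  n <- nrow(registry)
  with_seed(seed, {
    u <- stats::runif(n)
    miss <- u < corruption$p_missing_all
    n_inc <- sum(u >= corruption$p_missing_all &
                   u < corruption$p_missing_all + corruption$p_inconsistent)

    by <- birth_years(registry)
    dy <- death_years(registry)
    eligible <- which(!miss &
                        (by > years[1] | (!is.na(dy) & dy < years[length(years)])))
    if (corruption$p_inconsistent > 0 && !length(eligible)) {
      warning("p_inconsistent > 0 but no person has out-of-life window years; ",
              "no inconsistency injected", call. = FALSE)
      n_inc <- 0L
    }
    if (n_inc > length(eligible)) {
      warning("fewer eligible persons (", length(eligible),
              ") than inconsistency targets (", n_inc, ")", call. = FALSE)
      n_inc <- length(eligible)
    }
    chosen <- if (n_inc > 0) {
      if (length(eligible) == 1L) eligible else sample(eligible, n_inc)
    } else integer(0)

    dyi <- dy
    dyi[is.na(dyi)] <- .Machine$integer.max
    for (i in chosen) {
      out_idx <- which(years < by[i] | years > dyi[i])
      t <- if (length(out_idx) == 1L) out_idx else sample(out_idx, 1L)
      own <- pcm[i, ][pcm[i, ] != ""]
      pcm[i, t] <- own[1]
    }
    pcm[miss, ] <- ""
    set_postal_matrix(registry, pcm)
  })
}

#' Aggregate a registry into per-cell population counts
#'
#' Groups persons alive at `reference_year` (those with a real postal code
#' in that year's snapshot) by postal code, birth year and gender.
#'
#' @param registry A `registry`.
#' @param reference_year A window year.
#' @param universe Optional [build_postal_universe()] used to fill the
#'   urban flag; codes not found (or no universe) are flagged urban.
#' @return An `aggregate_counts` data frame with columns `postal_code`,
#'   `birth_year`, `gender`, `count`, `urban`.
#' @export
aggregate_counts_from_registry <- function(registry, reference_year,
                                           universe = NULL) {
  years <- registry_window(registry)
  if (!(reference_year %in% years)) {
    stop("`reference_year` must lie inside the registry window", call. = FALSE)
  }
  code <- registry[[paste0("pc_", reference_year)]]
  code[is.na(code)] <- ""
  alive <- code != "" & !is_sentinel(code)
  df <- data.frame(postal_code = code[alive],
                   birth_year = birth_years(registry)[alive],
                   gender = registry$gender[alive],
                   stringsAsFactors = FALSE)
  if (!nrow(df)) stop("no person alive at the reference year", call. = FALSE)
  key <- paste(df$postal_code, df$birth_year, df$gender, sep = "\r")
  first <- !duplicated(key)
  out <- df[first, , drop = FALSE]
  out$count <- tabulate(match(key, key[first]))
  urban <- rep(1L, nrow(out))
  if (!is.null(universe)) {
    hit <- match(out$postal_code, universe$code)
    urban <- ifelse(!is.na(hit) & !universe$urban[hit], 0L, 1L)
  }
  out$urban <- urban
  rownames(out) <- NULL
  structure(out, reference_year = reference_year,
            class = c("aggregate_counts", "data.frame"))
}

#' Count realized address changes per person
#'
#' Number of change points between consecutive non-empty, non-sentinel
#' postal snapshots of each person's trail; the realized counterpart of
#' the mobility model's move-count distribution.
#'
#' @param registry A `registry`.
#' @return Integer vector, one count per person.
#' @export
count_address_changes <- function(registry) {
  pcm <- postal_matrix(registry)
  pcm[is_sentinel(pcm)] <- ""
  n <- nrow(pcm)
  changes <- integer(n)
  if (ncol(pcm) < 2) return(changes)
  for (t in 2:ncol(pcm)) {
    changes <- changes + (pcm[, t] != "" & pcm[, t - 1L] != "" &
                            pcm[, t] != pcm[, t - 1L])
  }
  changes
}
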