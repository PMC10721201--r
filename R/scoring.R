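#' Score a solicitation into bout / rejection / attempt
#'
#' A solicitation is scored a successful `bout` when the offspring suckled
#' for 5 s or more; a `rejection` when it suckled for less than 5 s and the
#' termination was due to the female; and an `attempt` when the offspring
#' brought its muzzle within a head of the udder but never suckled because
#' the female prevented access.
#'
#' @param suckle_duration_s Suckling duration in seconds; `NA` or 0 means
#'   the offspring never suckled.
#' @param terminated_by_female Logical: did the female end the contact?
#' @param approached_within_head Logical: did the offspring approach within
#'   a head of the udder (a precondition for scoring at all)?
#' @return Character vector with values `"bout"`, `"rejection"`, `"attempt"`.
#' @export
classify_solicitation <- function(suckle_duration_s, terminated_by_female,
                                  approached_within_head = TRUE) {
  if (any(suckle_duration_s < 0, na.rm = TRUE)) {
    stop("suckle duration cannot be negative")
  }
  if (any(!approached_within_head)) {
    stop("only approaches within a head of the udder are scored as solicitations")
  }
  n <- max(length(suckle_duration_s), length(terminated_by_female))
  dur <- rep_len(suckle_duration_s, n)
  term <- rep_len(terminated_by_female, n)
  out <- rep(NA_character_, n)
  suckled <- !is.na(dur) & dur > 0
  out[suckled & dur >= 5] <- "bout"
  out[suckled & dur < 5 & term] <- "rejection"
  out[!suckled] <- "attempt"
  if (anyNA(out)) {
    stop("short suckling not terminated by the female cannot be scored; ",
         "a < 5 s episode is a rejection only when the female ended it")
  }
  out
}

#' Merge suckling episodes of one female-offspring pair into bouts
#'
#' Successive suckling episodes of the same pair separated by a contact gap
#' of less than 20 s belong to one bout (durations are summed, the gap is
#' not counted); a gap of 20 s or more terminates the bout.
#'
#' @param episodes Data frame of chronological episodes for a single
#'   female-offspring pair with `start_time`, `end_time` (POSIXct) and
#'   `duration_s`.
#' @param gap_s Termination gap in seconds (default 20).
#' @return The merged episodes, one row per bout; `end_time` is the last
#'   fragment's end, `duration_s` the summed suckling time.
#' @export
merge_bout_fragments <- function(episodes, gap_s = 20) {
  if (nrow(episodes) <= 1) return(episodes)
  if (is.unsorted(as.numeric(episodes$start_time))) {
    stop("episodes must be sorted chronologically by start_time")
  }
  gaps <- as.numeric(episodes$start_time[-1]) - as.numeric(episodes$end_time[-nrow(episodes)])
  if (any(gaps < 0)) stop("overlapping suckling episodes for the same pair")
  bout_id <- cumsum(c(1, gaps >= gap_s))
  keep <- !duplicated(bout_id)
  merged <- episodes[keep, , drop = FALSE]
  merged$end_time <- as.POSIXct(as.vector(tapply(as.numeric(episodes$end_time),
                                                 bout_id, max)),
                                origin = "1970-01-01", tz = "UTC")
  merged$duration_s <- as.vector(tapply(episodes$duration_s, bout_id, sum))
  merged
}

#' Offspring-sex similarity indicator
#'
#' @param sex_a,sex_b Offspring sexes, `"M"` or `"F"`.
#' @return 1 when the sexes are the same, 0 when they differ.
#' @export
sex_similarity <- function(sex_a, sex_b) {
  ok <- c("M", "F")
  if (!all(sex_a %in% ok) || !all(sex_b %in% ok)) {
    stop("offspring sex must be 'M' or 'F'")
  }
  as.integer(sex_a == sex_b)
}

# Map each offspring to its mother; error on unknown offspring.
offspring_mother <- function(offspring_id, mothers) {
  idx <- match(offspring_id, mothers$offspring_id)
  if (anyNA(idx)) {
    stop("offspring with no known mother: ",
         paste(unique(offspring_id[is.na(idx)]), collapse = ", "))
  }
  mothers$mother_id[idx]
}

# Derive (or validate) the filial flag: the nursing female is the
# offspring's own mother.
filial_flag <- function(events, mothers) {
  events$female_id == offspring_mother(events$offspring_id, mothers)
}

#' Aggregate scored events into the ordered-dyad help table
#'
#' Sums successful non-filial bouts within ordered dyads: `a_ij` is the
#' number of allonursing bouts mother `i` (the lactating female) gave to
#' mother `j`'s offspring. Every ordered pair of distinct mothers gets a
#' row (zero count included), with the model covariates and the unordered
#' dyad's RAFI attached. Filial nursing is excluded from `a_ij` but is
#' untouched in the event stream for nursing summaries.
#'
#' @param events Canonical solicitation events (see [read_events()]).
#' @param mothers Mother attribute table with `mother_id`, `rank`,
#'   `age_years`, `offspring_id`, `offspring_sex`, `offspring_birth_mass`.
#' @param relatedness Symmetric relatedness matrix with mother ids as
#'   dimnames (see [read_relatedness()]).
#' @param signed_birth_mass If `TRUE` use the signed giver-minus-receiver
#'   birth-mass difference instead of the absolute difference (the default,
#'   for consistency with the absolute rank difference).
#' @return Tibble with one row per ordered pair: `giver_id`, `receiver_id`,
#'   `a_ij` (help given), `received` (help received from the same partner,
#'   `a_ji`), `r`, `abs_rank_diff`, `sex_similarity`, `birth_mass_diff`,
#'   `abs_age_diff`, `rafi`.
#' @export
build_dyad_table <- function(events, mothers, relatedness,
                             signed_birth_mass = FALSE) {
  ids <- mothers$mother_id
  stopifnot(!anyDuplicated(ids))
  if (!all(ids %in% rownames(relatedness))) {
    stop("relatedness matrix does not cover all mothers")
  }
  ev <- events
  ev$receiver <- offspring_mother(ev$offspring_id, mothers)
  if (!all(ev$female_id %in% ids)) {
    stop("event with lactating female not in the mother table")
  }
  allo <- ev[ev$outcome == "bout" & ev$female_id != ev$receiver, , drop = FALSE]

  grid <- expand.grid(giver_id = ids, receiver_id = ids,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  grid <- grid[grid$giver_id != grid$receiver_id, , drop = FALSE]
  counts <- table(factor(allo$female_id, ids), factor(allo$receiver, ids))
  grid$a_ij <- as.integer(counts[cbind(grid$giver_id, grid$receiver_id)])

  gi <- match(grid$giver_id, ids)
  re <- match(grid$receiver_id, ids)
  grid$r <- relatedness[cbind(grid$giver_id, grid$receiver_id)]
  grid$abs_rank_diff <- abs(mothers$rank[gi] - mothers$rank[re])
  grid$sex_similarity <- sex_similarity(mothers$offspring_sex[gi],
                                        mothers$offspring_sex[re])
  bm <- mothers$offspring_birth_mass[gi] - mothers$offspring_birth_mass[re]
  grid$birth_mass_diff <- if (signed_birth_mass) bm else abs(bm)
  grid$abs_age_diff <- abs(mothers$age_years[gi] - mothers$age_years[re])
  grid$received <- as.integer(counts[cbind(grid$receiver_id, grid$giver_id)])
  grid$rafi <- rafi(grid$a_ij, as.numeric(grid$received))
  tibble::as_tibble(grid)
}

#' Per-mother totals of help given and received
#'
#' @param events Canonical solicitation events.
#' @param mothers Mother attribute table.
#' @param observation_days Number of observation days for the group (the
#'   exposure offset base for the generalized-reciprocity model).
#' @return Tibble `mother_id`, `total_given`, `total_received`,
#'   `observation_days`.
#' @export
mother_totals <- function(events, mothers, observation_days) {
  stopifnot(observation_days >= 1)
  ev <- events
  ev$receiver <- offspring_mother(ev$offspring_id, mothers)
  allo <- ev[ev$outcome == "bout" & ev$female_id != ev$receiver, , drop = FALSE]
  ids <- mothers$mother_id
  tibble::tibble(
    mother_id = ids,
    total_given = as.integer(table(factor(allo$female_id, ids))),
    total_received = as.integer(table(factor(allo$receiver, ids))),
    observation_days = observation_days
  )
}

#' Per-solicitation table for the likelihood-of-allonursing models
#'
#' One row per non-filial solicitation (bout, rejection or attempt) with
#' the binary success indicator and the dyad covariates used by the
#' logistic models: the unordered dyad's RAFI, relatedness, the solicited
#' offspring's sex, absolute rank difference and birth-mass difference.
#'
#' @inheritParams build_dyad_table
#' @return Tibble with `female_id` (the solicited lactating female),
#'   `receiver_id` (the soliciting offspring's mother), `success`,
#'   `rafi`, `r`, `offspring_sex`, `abs_rank_diff`, `birth_mass_diff`.
#' @export
build_likelihood_table <- function(events, mothers, relatedness,
                                   signed_birth_mass = FALSE) {
  dyads <- build_dyad_table(events, mothers, relatedness,
                            signed_birth_mass = signed_birth_mass)
  ev <- events
  ev$receiver_id <- offspring_mother(ev$offspring_id, mothers)
  ev <- ev[ev$female_id != ev$receiver_id, , drop = FALSE]
  key <- paste(ev$female_id, ev$receiver_id)
  dkey <- paste(dyads$giver_id, dyads$receiver_id)
  idx <- match(key, dkey)
  oi <- match(ev$offspring_id, mothers$offspring_id)
  tibble::tibble(
    female_id = ev$female_id,
    receiver_id = ev$receiver_id,
    success = as.integer(ev$outcome == "bout"),
    rafi = dyads$rafi[idx],
    r = dyads$r[idx],
    offspring_sex = mothers$offspring_sex[oi],
    abs_rank_diff = dyads$abs_rank_diff[idx],
    birth_mass_diff = dyads$birth_mass_diff[idx]
  )
}
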