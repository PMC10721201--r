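# Shared fixtures and independent brute-force oracles.
#
# The oracles deliberately use naive row-by-row loops, independent of the
# package's vectorized implementations.

ts <- function(x) as.POSIXct(x, tz = "UTC")

# Compact event constructor: one row per solicitation.
make_events <- function(female, offspring, start, outcome,
                        duration = NA_real_, end = NA, group = "G1") {
  n <- max(length(female), length(offspring), length(start), length(outcome))
  end_time <- if (all(is.na(end))) as.POSIXct(rep(NA_character_, n), tz = "UTC") else ts(end)
  tibble::tibble(
    group_id = group,
    female_id = rep_len(female, n),
    offspring_id = rep_len(offspring, n),
    start_time = ts(start),
    end_time = end_time,
    duration_s = rep_len(duration, n),
    outcome = rep_len(outcome, n),
    is_filial = NA
  )
}

# n mothers M1..Mn with offspring O1..On, ranks 1..n.
make_mothers <- function(n, group = "G1", sexes = NULL, masses = NULL,
                         ages = NULL) {
  tibble::tibble(
    mother_id = paste0("M", seq_len(n)),
    group_id = group,
    age_years = ages %||% rep(5, n),
    rank = seq_len(n),
    offspring_id = paste0("O", seq_len(n)),
    offspring_sex = sexes %||% rep(c("M", "F"), length.out = n),
    offspring_birth_mass = masses %||% seq(5, by = 0.5, length.out = n),
    offspring_birth_date = as.Date("2012-05-05") + seq_len(n)
  )
}

make_relatedness <- function(n, value = 0.1) {
  ids <- paste0("M", seq_len(n))
  m <- matrix(value, n, n, dimnames = list(ids, ids))
  diag(m) <- NA_real_
  m
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Brute-force tally of non-filial bouts per ordered mother pair.
oracle_dyad_counts <- function(events, mothers) {
  ids <- mothers$mother_id
  counts <- matrix(0L, length(ids), length(ids), dimnames = list(ids, ids))
  for (k in seq_len(nrow(events))) {
    if (events$outcome[k] != "bout") next
    giver <- events$female_id[k]
    receiver <- mothers$mother_id[mothers$offspring_id == events$offspring_id[k]]
    if (giver == receiver) next
    counts[giver, receiver] <- counts[giver, receiver] + 1L
  }
  counts
}

# Brute-force latency scan: for every given bout, search all receipts.
oracle_latencies <- function(events, mothers, rule) {
  ev <- allonurse::impute_bout_end(events)
  rec_of <- function(off) mothers$mother_id[mothers$offspring_id == off]
  bouts <- ev[ev$outcome == "bout", , drop = FALSE]
  bouts$receiver <- vapply(bouts$offspring_id, rec_of, character(1))
  bouts <- bouts[bouts$female_id != bouts$receiver, , drop = FALSE]
  out <- numeric(0)
  for (k in seq_len(nrow(bouts))) {
    giver <- bouts$female_id[k]
    partner <- bouts$receiver[k]
    best <- -Inf
    for (m in seq_len(nrow(bouts))) {
      if (bouts$receiver[m] != giver) next
      if (rule == "direct" && bouts$female_id[m] != partner) next
      if (as.numeric(bouts$end_time[m]) <= as.numeric(bouts$start_time[k]) &&
          as.numeric(bouts$end_time[m]) > best) {
        best <- as.numeric(bouts$end_time[m])
      }
    }
    if (is.finite(best)) {
      lat <- (as.numeric(bouts$start_time[k]) - best) / 86400
      if (lat > 0) out <- c(out, lat)
    }
  }
  sort(out)
}

# Brute-force Landau h: direct evaluation of the V_a sum.
oracle_landau <- function(m) {
  n <- nrow(m)
  v <- numeric(n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    if (m[i, j] > m[j, i]) v[i] <- v[i] + 1
    if (m[i, j] == m[j, i]) v[i] <- v[i] + 0.5
  }
  12 / (n^3 - n) * sum((v - (n - 1) / 2)^2)
}
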