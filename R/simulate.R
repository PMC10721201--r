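#' Configuration for the allonursing decision-rule simulator
#'
#' Defaults emulate the 2012 study group: 25 mother-offspring pairs
#' observed for 65 days, with four 1 h observation sessions per day, a
#' solicitation pressure and baseline acceptance tuned to yield on the
#' order of 1400 allonursing bouts per season, allonursing bout durations
#' lognormal around 15 s and filial nursing around 40 s, and a relatedness
#' matrix centred on the 2012 group mean (-0.009, range -0.144 to 0.239).
#' The three decision rules enter acceptance on the logit scale as
#' orthogonal, switchable boosts:
#' `logit(p) = logit(p_base) + delta_direct * [partner previously helped me]`
#' `+ gamma_generalized * [anyone helped me within tau_days] + kappa_kin * r`.
#'
#' @param n_mothers Number of mother-offspring pairs.
#' @param observation_days Observation days in the season.
#' @param sessions_per_day,session_hours Daily observation window geometry.
#' @param solicitations_per_offspring_per_day Poisson rate of non-filial
#'   solicitations per offspring-day.
#' @param p_base Baseline acceptance probability of a non-filial
#'   solicitation.
#' @param delta_direct Log-odds acceptance boost when the soliciting
#'   offspring's mother previously helped the focal mother.
#' @param gamma_generalized Log-odds boost when the focal mother received
#'   any help within the last `tau_days` days.
#' @param tau_days Memory window of the generalized rule, days.
#' @param kappa_kin Log-odds slope of acceptance on pairwise relatedness.
#' @param theft_rate Probability that a refused solicitation nevertheless
#'   becomes a stolen bout (milk theft, independent of the female's
#'   decision).
#' @param rejection_share Among refused, non-stolen solicitations, the
#'   share scored `rejection` (brief suckling ended by the female) rather
#'   than `attempt`.
#' @param filial_nursing_rate Poisson rate of own-offspring nursing bouts
#'   per offspring-day.
#' @param mean_bout_s,sd_bout_s Allonursing bout duration (lognormal
#'   moments, seconds).
#' @param filial_mean_bout_s,filial_sd_bout_s Filial bout duration moments.
#' @param relatedness_mean,relatedness_sd,relatedness_range Targets for the
#'   simulated pairwise relatedness matrix.
#' @param agonistic_per_pair Expected resolved agonistic interactions per
#'   unordered pair over the season.
#' @param unresolved_rate Share of agonistic interactions left unresolved.
#' @param hierarchy_steepness Logit slope of win probability on latent
#'   rank difference.
#' @param group_id,year Labels carried into the generated tables.
#' @param start_date First observation day.
#' @param seed Integer seed; identical config + seed gives bit-identical
#'   output.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_mothers = 25, observation_days = 65,
                       sessions_per_day = 4, session_hours = 1,
                       solicitations_per_offspring_per_day = 2.5,
                       p_base = 0.33, delta_direct = 0,
                       gamma_generalized = 0, tau_days = 1,
                       kappa_kin = 0, theft_rate = 0.05,
                       rejection_share = 0.5,
                       filial_nursing_rate = 3,
                       mean_bout_s = 15, sd_bout_s = 9,
                       filial_mean_bout_s = 40, filial_sd_bout_s = 20,
                       relatedness_mean = -0.009, relatedness_sd = 0.052,
                       relatedness_range = c(-0.144, 0.239),
                       agonistic_per_pair = 15, unresolved_rate = 0.1,
                       hierarchy_steepness = 0.6,
                       group_id = "G2012", year = 2012L,
                       start_date = "2012-05-15", seed = 1L) {
  cfg <- as.list(environment())
  stopifnot(n_mothers >= 2, observation_days >= 1,
            p_base > 0, p_base < 1, tau_days > 0,
            theft_rate >= 0, theft_rate <= 1,
            relatedness_range[1] <= relatedness_mean,
            relatedness_mean <= relatedness_range[2])
  structure(cfg, class = "sim_config")
}

#' Simulate a pairwise relatedness matrix
#'
#' Off-diagonal values are drawn iid normal around the target mean and
#' clipped to the target range; the matrix is symmetric with an `NA`
#' diagonal. With enough pairs the sample mean lies within two standard
#' errors of the target.
#'
#' @param n Number of individuals.
#' @param mean,sd,range Targets for the off-diagonal values.
#' @param ids Optional id labels (default `M01..`).
#' @param seed Optional seed (set only if non-NULL, so the function can
#'   also run inside an already-seeded simulation).
#' @return Symmetric numeric matrix with `NA` diagonal.
#' @export
simulate_relatedness <- function(n, mean = -0.009, sd = 0.052,
                                 range = c(-0.144, 0.239), ids = NULL,
                                 seed = NULL) {
  if (mean < range[1] || mean > range[2]) {
    stop("target mean lies outside the target range")
  }
  if (!is.null(seed)) set.seed(seed)
  if (is.null(ids)) ids <- sprintf("M%02d", seq_len(n))
  m <- matrix(NA_real_, n, n, dimnames = list(ids, ids))
  ut <- upper.tri(m)
  vals <- pmin(pmax(rnorm(sum(ut), mean, sd), range[1]), range[2])
  m[ut] <- vals
  m[lower.tri(m)] <- t(m)[lower.tri(m)]
  m
}

rlnorm_moments <- function(n, mean, sd) {
  s2 <- log(1 + (sd / mean)^2)
  rlnorm(n, meanlog = log(mean) - s2 / 2, sdlog = sqrt(s2))
}

#' Simulate a full allonursing study group
#'
#' Generates mother attributes, a relatedness matrix, an agonistic log
#' from a latent linear hierarchy, and a chronological solicitation event
#' stream in which each non-filial solicitation is accepted with the
#' configured decision-rule probability (see [sim_config()]). Refused
#' solicitations become rejections or attempts; a fraction become stolen
#' bouts regardless of the female's decision. Everything a reader consumes
#' is in the same canonical shapes the readers produce.
#'
#' @param config A [sim_config()].
#' @return A `sim_output` list: `events`, `mothers`, `relatedness`,
#'   `agonistic`, `group_info`, `truth` (the config) and `counters`
#'   (the simulator's internal ordered-dyad bout tally, for conservation
#'   checks).
#' @export
simulate_group <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n <- config$n_mothers
  ids <- sprintf("M%02d", seq_len(n))
  off <- sprintf("O%02d", seq_len(n))
  day0 <- as.POSIXct(paste(config$start_date, "08:00:00"), tz = "UTC")

  mothers <- tibble::tibble(
    mother_id = ids, group_id = config$group_id,
    age_years = sample(3:12, n, replace = TRUE),
    rank = seq_len(n),  # latent rank; re-derived from agonistic data downstream
    offspring_id = off,
    offspring_sex = sample(c("M", "F"), n, replace = TRUE),
    offspring_birth_mass = round(rnorm(n, 6, 0.8), 2),
    offspring_birth_date = as.Date(config$start_date) - sample(3:12, n, replace = TRUE)
  )
  relmat <- simulate_relatedness(n, config$relatedness_mean,
                                 config$relatedness_sd,
                                 config$relatedness_range, ids = ids)

  # agonistic log from the latent hierarchy
  pairs <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  ag <- vector("list", nrow(pairs))
  for (k in seq_len(nrow(pairs))) {
    i <- pairs[k, 1]; j <- pairs[k, 2]
    m <- rpois(1, config$agonistic_per_pair)
    if (m == 0) next
    unres <- runif(m) < config$unresolved_rate
    p_i <- plogis(config$hierarchy_steepness * (mothers$rank[i] - mothers$rank[j]))
    i_wins <- runif(m) < p_i
    ag[[k]] <- tibble::tibble(
      group_id = config$group_id, individual_a = ids[i], individual_b = ids[j],
      winner = ifelse(unres, NA_character_, ifelse(i_wins, ids[i], ids[j])),
      resolved = !unres
    )
  }
  agonistic <- dplyr::bind_rows(ag)

  # candidate solicitations: times uniform in the daily observation window
  window_s <- config$sessions_per_day * config$session_hours * 3600
  days <- config$observation_days
  grid_day <- rep(seq_len(days), each = n)
  grid_off <- rep(seq_len(n), times = days)
  k_allo <- rpois(n * days, config$solicitations_per_offspring_per_day)
  k_fil <- rpois(n * days, config$filial_nursing_rate)
  allo_off <- rep(grid_off, k_allo)
  # target female uniform among the other mothers
  allo_fem <- 1L + ((allo_off - 1L + sample.int(n - 1L, length(allo_off),
                                                replace = TRUE)) %% n)
  fil_off <- rep(grid_off, k_fil)
  cand <- data.frame(
    t = round(runif(length(allo_off) + length(fil_off), 0, window_s)),
    off = c(allo_off, fil_off),
    fem = c(allo_fem, fil_off),
    filial = rep(c(FALSE, TRUE), c(length(allo_off), length(fil_off))),
    day = c(rep(grid_day, k_allo), rep(grid_day, k_fil))
  )
  cand$abs_t <- (cand$day - 1) * 86400 + cand$t
  cand <- cand[order(cand$abs_t), , drop = FALSE]
  m_cand <- nrow(cand)

  helped <- matrix(FALSE, n, n)      # helped[i, j]: i has allonursed j's offspring
  last_received <- rep(-Inf, n)      # time (s) each mother last received help
  a_count <- matrix(0L, n, n, dimnames = list(ids, ids))
  tau_s <- config$tau_days * 86400
  lq <- qlogis(config$p_base)

  # all stochastic draws made up front; the sequential pass only tracks the
  # decision-rule state (who helped whom, time of last help received)
  u_accept <- runif(m_cand)
  u_theft <- runif(m_cand)
  u_reject <- runif(m_cand)
  dur_bout <- pmax(5, rlnorm_moments(m_cand, config$mean_bout_s, config$sd_bout_s))
  dur_fil <- pmax(5, rlnorm_moments(m_cand, config$filial_mean_bout_s,
                                    config$filial_sd_bout_s))
  dur_rej <- runif(m_cand, 0.5, 4.9)
  r_pair <- relmat[cbind(cand$fem, cand$off)]

  outcome <- character(m_cand)
  duration <- numeric(m_cand)
  for (k in seq_len(m_cand)) {
    fem <- cand$fem[k]; off_m <- cand$off[k]; now <- cand$abs_t[k]
    if (cand$filial[k]) {
      outcome[k] <- "bout"
      duration[k] <- dur_fil[k]
      next
    }
    eta <- lq +
      config$delta_direct * helped[off_m, fem] +
      config$gamma_generalized * ((now - last_received[fem]) <= tau_s) +
      config$kappa_kin * r_pair[k]
    accept <- u_accept[k] < plogis(eta)
    stolen <- !accept && u_theft[k] < config$theft_rate
    if (accept || stolen) {
      outcome[k] <- "bout"
      duration[k] <- dur_bout[k]
      helped[fem, off_m] <- TRUE
      a_count[fem, off_m] <- a_count[fem, off_m] + 1L
      last_received[off_m] <- now + duration[k]
    } else if (u_reject[k] < config$rejection_share) {
      outcome[k] <- "rejection"
      duration[k] <- dur_rej[k]
    } else {
      outcome[k] <- "attempt"
      duration[k] <- NA_real_
    }
  }

  events <- tibble::tibble(
    group_id = config$group_id,
    female_id = ids[cand$fem],
    offspring_id = off[cand$off],
    start_time = day0 + cand$abs_t,
    end_time = day0 + cand$abs_t + ifelse(is.na(duration), 0, round(duration)),
    duration_s = round(duration, 1),
    outcome = outcome,
    is_filial = cand$filial
  )
  events$end_time[events$outcome == "attempt"] <- events$start_time[events$outcome == "attempt"]

  group_info <- tibble::tibble(
    group_id = config$group_id, year = config$year, n_mothers = n,
    observation_days = config$observation_days,
    relatedness_class = "unselected"
  )
  structure(list(events = events, mothers = mothers, relatedness = relmat,
                 agonistic = agonistic, group_info = group_info,
                 truth = config, counters = a_count),
            class = "sim_output")
}

#' @export
print.sim_output <- function(x, ...) {
  cat(sprintf("sim_output: group %s, %d mothers, %d days\n",
              x$group_info$group_id, x$group_info$n_mothers,
              x$group_info$observation_days))
  cat(sprintf("  %d solicitations (%d allonursing bouts), %d agonistic interactions\n",
              nrow(x$events), sum(x$counters), nrow(x$agonistic)))
  invisible(x)
}

#' Run the full pipeline on simulated data and compare with the truth
#'
#' Executes scoring, dyad aggregation, RAFI, dominance, the count and
#' latency analyses on a [simulate_group()] output and reports, for each
#' decision-rule parameter, the generating value, the matched estimate
#' (log scale), its Wald CI, whether the CI covers zero and whether a
#' positive effect was detected at alpha = 0.05.
#'
#' @param sim A `sim_output`.
#' @param alpha Detection level.
#' @return Tibble: `parameter`, `truth`, `estimate`, `se`, `p`, `ci_low`,
#'   `ci_high`, `covers_zero`, `detected_positive`.
#' @export
recover_parameters <- function(sim, alpha = 0.05) {
  stopifnot(inherits(sim, "sim_output"))
  bundle <- run_group(sim, run_influence = FALSE)
  cf <- bundle$fits$count_main$coefficients
  row_of <- function(term) cf[cf$term == term, , drop = FALSE]
  pull <- function(term, truth, parameter) {
    rw <- row_of(term)
    tibble::tibble(
      parameter = parameter, truth = truth,
      estimate = rw$estimate, se = rw$se, p = rw$p,
      ci_low = rw$estimate - Z95 * rw$se,
      ci_high = rw$estimate + Z95 * rw$se
    )
  }
  out <- dplyr::bind_rows(
    pull("received", sim$truth$delta_direct, "delta_direct (via received)"),
    pull("r", sim$truth$kappa_kin, "kappa_kin (via relatedness)")
  )

  # generalized rule: latency contrast between the two pairing rules
  lat <- dplyr::bind_rows(
    direct_latencies(sim$events, sim$mothers, sim$relatedness,
                     year = sim$group_info$year),
    generalized_latencies(sim$events, sim$mothers, sim$relatedness,
                          year = sim$group_info$year)
  )
  if (length(unique(lat$rule)) == 2) {
    cmp <- compare_rules(lat)
    rc <- cmp$fit$coefficients
    rw <- rc[rc$term == "rulegeneralized", , drop = FALSE]
    out <- dplyr::bind_rows(out, tibble::tibble(
      parameter = "gamma_generalized (via latency contrast)",
      truth = sim$truth$gamma_generalized,
      estimate = rw$estimate, se = rw$se, p = rw$p,
      ci_low = rw$estimate - Z95 * rw$se,
      ci_high = rw$estimate + Z95 * rw$se
    ))
  }
  out$covers_zero <- out$ci_low <= 0 & out$ci_high >= 0
  out$detected_positive <- out$p < alpha & out$estimate > 0
  out
}
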