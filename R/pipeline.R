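#' Run the per-group decision-rule analysis
#'
#' Executes, in order: rank assignment from the agonistic log (with
#' Landau's linearity index), dyadic aggregation, RAFI, the count models
#' for help given (interaction between help received and relatedness
#' first; the interaction is dropped when non-significant at
#' `alpha`), the RAFI >= 0.5 subset count model (when the subset is large
#' enough), the likelihood-of-allonursing logistic models (same branch
#' logic on the RAFI x relatedness interaction), the RAFI-response count
#' model, the overdispersion check with negative-binomial refits, and the
#' latency records. Every branch taken is recorded in the bundle's `log`.
#'
#' @param group A list (or `sim_output`) with `events`, `mothers`,
#'   `relatedness`, `agonistic` (optional), `group_info`.
#' @param alpha Significance level for the interaction branch (default
#'   0.05).
#' @param dispersion_threshold Pearson-dispersion threshold for the
#'   negative-binomial refit (default 1.5).
#' @param min_subset Minimum number of reciprocal dyads (RAFI >= 0.5)
#'   needed to fit the subset model (default 10).
#' @param run_influence Run the (refit-based, slow) case-deletion
#'   influence diagnostics.
#' @return A [results_bundle()] with fits keyed `count_interaction`,
#'   `count_main`, `count_rafi_subset`, `likelihood_interaction`,
#'   `likelihood_main`, `rafi_response` (negative-binomial refits replace
#'   the Poisson fit, noted in the log), plus the dyad table, ranks,
#'   Landau's h, diagnostics and latency records under `extra`.
#' @export
run_group <- function(group, alpha = 0.05, dispersion_threshold = 1.5,
                      min_subset = 10, run_influence = FALSE) {
  gi <- group$group_info
  log_lines <- character()
  note <- function(...) log_lines <<- c(log_lines, sprintf(...))

  mothers <- group$mothers
  landau <- NA_real_
  if (!is.null(group$agonistic) && nrow(group$agonistic) > 0) {
    wl <- win_loss_matrix(group$agonistic, ids = mothers$mother_id)
    ranks <- assign_ranks(wl)
    mothers$rank <- unname(ranks[mothers$mother_id])
    landau <- landau_h(wl)
    note("ranks assigned from %d agonistic interactions; Landau h = %.3f",
         nrow(group$agonistic), landau)
  } else {
    note("no agonistic log supplied; using ranks from the mother table")
  }

  dyads <- build_dyad_table(group$events, mothers, group$relatedness)
  note("dyad table: %d ordered pairs, %d allonursing bouts",
       nrow(dyads), sum(dyads$a_ij))

  fits <- list()
  diagnostics <- list()

  # --- count models: help given ~ help received x relatedness -------------
  count_rand <- c("giver_id", "receiver_id")
  ctrl <- c("abs_rank_diff", "sex_similarity", "birth_mass_diff")
  fit_int <- fit_glmm(model_spec("a_ij", "poisson",
                                 fixed = c("received * r", ctrl),
                                 random = count_rand), dyads)
  fits$count_interaction <- fit_int
  p_int <- fit_int$coefficients$p[fit_int$coefficients$term == "received:r"]
  if (length(p_int) == 1 && !is.na(p_int) && p_int < alpha) {
    note("received x relatedness interaction significant (p = %.3g); kept", p_int)
    fits$count_main <- fit_int
  } else {
    note("received x relatedness interaction not significant (p = %.3g); dropped", p_int)
    fits$count_main <- fit_glmm(model_spec("a_ij", "poisson",
                                           fixed = c("received", "r", ctrl),
                                           random = count_rand), dyads)
  }
  od <- check_overdispersion(fits$count_main, dispersion_threshold)
  if (od$overdispersed) {
    note("count model overdispersed (%.2f > %.2f); refit with negative binomial",
         od$ratio, od$threshold)
    fits$count_main <- fit_glmm(model_spec("a_ij", "nb",
                                           fixed = fits$count_main$spec$fixed,
                                           random = count_rand), dyads)
  }
  diagnostics$count_dispersion <- od

  # --- RAFI >= 0.5 subset (dyads with a tendency to reciprocate) ----------
  subset <- dyads[!is.na(dyads$rafi) & dyads$rafi >= 0.5, , drop = FALSE]
  note("%d ordered dyad records with RAFI >= 0.5", nrow(subset))
  if (nrow(subset) >= min_subset &&
      length(unique(subset$giver_id)) >= 2 &&
      length(unique(subset$receiver_id)) >= 2) {
    fits$count_rafi_subset <- fit_glmm(
      model_spec("a_ij", "poisson", fixed = c("received", "r", ctrl),
                 random = count_rand), subset)
  } else {
    note("subset too small; RAFI >= 0.5 model skipped")
  }

  # --- likelihood of allonursing (per solicitation) -----------------------
  lik <- build_likelihood_table(group$events, mothers, group$relatedness)
  lik <- lik[!is.na(lik$rafi), , drop = FALSE]  # undefined RAFI excluded, not imputed
  note("likelihood table: %d solicitations on dyads with defined RAFI", nrow(lik))
  lik_rand <- c("female_id", "receiver_id")
  lik_ctrl <- c("offspring_sex", "abs_rank_diff", "birth_mass_diff")
  if (nrow(lik) >= 20 && length(unique(lik$success)) == 2) {
    fit_lint <- fit_glmm(model_spec("success", "binomial",
                                    fixed = c("rafi * r", lik_ctrl),
                                    random = lik_rand), lik)
    fits$likelihood_interaction <- fit_lint
    p_lint <- fit_lint$coefficients$p[fit_lint$coefficients$term == "rafi:r"]
    if (length(p_lint) == 1 && !is.na(p_lint) && p_lint < alpha) {
      note("RAFI x relatedness interaction significant (p = %.3g); kept", p_lint)
      fits$likelihood_main <- fit_lint
    } else {
      note("RAFI x relatedness interaction not significant (p = %.3g); dropped", p_lint)
      fits$likelihood_main <- fit_glmm(model_spec("success", "binomial",
                                                  fixed = c("rafi", "r", lik_ctrl),
                                                  random = lik_rand), lik)
    }
  } else {
    note("too few solicitations for the likelihood models")
  }

  # --- RAFI as response (unordered dyads, defined RAFI only) --------------
  unord <- dyads[dyads$giver_id < dyads$receiver_id & !is.na(dyads$rafi), , drop = FALSE]
  unord$rafi_count <- rafi_to_count(unord$rafi)
  if (nrow(unord) >= 10) {
    fit_rafi <- fit_glmm(model_spec("rafi_count", "poisson",
                                    fixed = c("r", "abs_rank_diff",
                                              "birth_mass_diff", "abs_age_diff"),
                                    random = count_rand), unord)
    odr <- check_overdispersion(fit_rafi, dispersion_threshold)
    if (odr$overdispersed) {
      note("RAFI response overdispersed (%.2f); negative-binomial refit", odr$ratio)
      fit_rafi <- fit_glmm(model_spec("rafi_count", "nb",
                                      fixed = fit_rafi$spec$fixed,
                                      random = count_rand), unord)
    }
    fits$rafi_response <- fit_rafi
    diagnostics$rafi_dispersion <- odr
  } else {
    note("too few defined-RAFI dyads for the RAFI response model")
  }

  # --- diagnostics --------------------------------------------------------
  n_mothers <- nrow(mothers)
  diagnostics$cutoffs <- influence_cutoffs(n_mothers)
  cont <- c("received", "r", "abs_rank_diff", "birth_mass_diff")
  diagnostics$outliers <- lapply(setNames(cont, cont), function(v) {
    suppressWarnings(which(zscore_outliers(dyads[[v]])))
  })
  diagnostics$vif <- tryCatch(vif_terms(fits$count_main),
                              error = function(e) NULL)
  if (run_influence) {
    diagnostics$influence <- influence_measures(fits$count_main, n_mothers)
  }

  # --- latencies ----------------------------------------------------------
  lat <- dplyr::bind_rows(
    direct_latencies(group$events, mothers, group$relatedness, year = gi$year),
    generalized_latencies(group$events, mothers, group$relatedness, year = gi$year)
  )

  bundle <- results_bundle(
    group_id = gi$group_id,
    fits = fits,
    latency = lat,
    diagnostics = diagnostics,
    extra = list(dyads = dyads, ranks = setNames(mothers$rank, mothers$mother_id),
                 landau_h = landau, log = log_lines,
                 group_info = gi)
  )
  bundle
}

#' Fit the generalized-reciprocity totals model across groups
#'
#' Pools per-mother totals of help given and received over all groups and
#' fits a Poisson mixed model of total help given on total help received
#' with a log observation-days offset and random intercepts for mother
#' identity and year; also runs the direct-vs-generalized latency
#' comparison on the pooled latency records.
#'
#' @param groups List of group lists (each with `events`, `mothers`,
#'   `relatedness`, `group_info`).
#' @param compare_latencies Also run [compare_rules()] on pooled records.
#' @return List: `totals` (the pooled per-mother table), `fit` (the offset
#'   Poisson `allonurse_fit`), `latency` (the [compare_rules()] result or
#'   `NULL`).
#' @export
run_generalized <- function(groups, compare_latencies = TRUE) {
  stopifnot(length(groups) >= 1)
  totals <- dplyr::bind_rows(lapply(groups, function(g) {
    if (nrow(g$mothers) < 2) stop("a group needs at least 2 mothers")
    tt <- mother_totals(g$events, g$mothers, g$group_info$observation_days)
    tt$year <- g$group_info$year
    tt
  }))
  if (sum(totals$total_given) == 0) stop("no allonursing bouts in the pooled data")
  random <- "mother_id"
  if (length(unique(totals$year)) > 1) random <- c(random, "year")
  fit <- fit_glmm(model_spec("total_given", "poisson", fixed = "total_received",
                             offset = "observation_days", random = random),
                  totals)
  lat_cmp <- NULL
  if (compare_latencies) {
    lat <- dplyr::bind_rows(lapply(groups, function(g) {
      dplyr::bind_rows(
        direct_latencies(g$events, g$mothers, g$relatedness,
                         year = g$group_info$year),
        generalized_latencies(g$events, g$mothers, g$relatedness,
                              year = g$group_info$year))
    }))
    if (length(unique(lat$rule)) == 2) lat_cmp <- compare_rules(lat)
  }
  list(totals = totals, fit = fit, latency = lat_cmp)
}

extract_effect <- function(bundle, fit_name, term, source) {
  fit <- bundle$fits[[fit_name]]
  if (is.null(fit)) return(NULL)
  cf <- as.data.frame(fit$coefficients)
  rw <- cf[cf$term == term, , drop = FALSE]
  if (nrow(rw) != 1) return(NULL)
  if (source == "model_se") {
    study_effects(bundle$group_id, effect_log = rw$estimate, se_log = rw$se,
                  source = "model_se")
  } else {
    ex <- as.data.frame(fit$exponentiated)
    er <- ex[ex$term == term, , drop = FALSE]
    study_effects(bundle$group_id, ratio = er$ratio, ci_low = er$ci_low,
                  ci_high = er$ci_high, source = "ci_derived")
  }
}

#' Pool the direct-reciprocity effects across groups
#'
#' Runs the two internal fixed-effect meta-analyses: the incidence rate
#' ratio of help given on help received (from each group's main-effects
#' count model) and the odds ratio of a successful allonursing attempt on
#' RAFI (from each group's main-effects likelihood model). A bundle
#' missing the relevant fit is excluded with a warning.
#'
#' @param bundles List of [run_group()] bundles.
#' @param source `"model_se"` (SEs straight from the fitted models) or
#'   `"ci_derived"` (back-calculated from the exponentiated CIs).
#' @return List: `irr` and `or` (each a `meta_result` plus its
#'   `study_effects` table and forest lines), either `NULL` when no group
#'   contributed.
#' @export
run_meta <- function(bundles, source = c("model_se", "ci_derived")) {
  source <- match.arg(source)
  pool_one <- function(fit_name, term) {
    effs <- list()
    for (b in bundles) {
      e <- extract_effect(b, fit_name, term, source)
      if (is.null(e)) {
        warning("group ", b$group_id, " lacks fit '", fit_name,
                "' (term ", term, "); excluded from pooling")
      } else {
        effs[[length(effs) + 1]] <- e
      }
    }
    if (length(effs) == 0) return(NULL)
    effects <- dplyr::bind_rows(effs)
    res <- pool_fixed(effects)
    list(effects = effects, result = res, forest = forest_table(effects, res))
  }
  list(irr = pool_one("count_main", "received"),
       or = pool_one("likelihood_main", "rafi"))
}
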