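#' Back-calculate a log-scale standard error from a printed ratio CI
#'
#' Recovers the standard error of a log incidence-rate ratio or log odds
#' ratio from its printed 95% confidence interval:
#' `se = (log(ci_high) - log(ci_low)) / (2 * 1.959964)`.
#'
#' @param ratio Point estimate on the ratio scale (IRR or OR).
#' @param ci_low,ci_high 95% confidence bounds on the ratio scale.
#' @return Standard error on the log scale.
#' @export
se_from_ci <- function(ratio, ci_low, ci_high) {
  if (any(ci_low <= 0) || any(ci_low > ratio) || any(ci_high < ratio)) {
    stop("confidence interval must be positive and bracket the ratio")
  }
  (log(ci_high) - log(ci_low)) / (2 * Z95)
}

#' Construct a table of study effects for pooling
#'
#' @param label Study labels.
#' @param ratio Effect sizes on the ratio scale (IRR/OR), or `NULL` if
#'   `effect_log` is given directly.
#' @param ci_low,ci_high Ratio-scale 95% CI bounds (used to derive SEs when
#'   `se_log` is not supplied).
#' @param effect_log,se_log Log-scale effect and SE (e.g. straight from a
#'   fitted model).
#' @param source Provenance of the SEs: `"ci_derived"` (back-calculated
#'   from printed CIs) or `"model_se"` (taken from the fitted models).
#' @return A tibble with columns `label`, `effect_log`, `se_log`, `source`.
#' @export
study_effects <- function(label, ratio = NULL, ci_low = NULL, ci_high = NULL,
                          effect_log = NULL, se_log = NULL,
                          source = if (is.null(se_log)) "ci_derived" else "model_se") {
  force(source)
  if (is.null(effect_log)) effect_log <- log(ratio)
  if (is.null(se_log)) se_log <- se_from_ci(ratio, ci_low, ci_high)
  if (any(se_log <= 0)) stop("standard errors must be positive")
  tibble::tibble(label = label, effect_log = effect_log, se_log = se_log,
                 source = source)
}

#' Fixed-effect inverse-variance pooling
#'
#' Pools log-scale effects with weights \eqn{w_i = 1/se_i^2}:
#' \eqn{\hat\theta = \sum w_i \theta_i / \sum w_i}, with pooled SE
#' \eqn{1/\sqrt{\sum w_i}}. Heterogeneity statistics (Q, tau-squared, I-squared,
#' H and their intervals) are attached when two or more studies are pooled.
#'
#' @param effects A `study_effects()` tibble (>= 1 row).
#' @param level Confidence level (default 0.95).
#' @return A `meta_result` list: `pooled_log`, `se_log`, `pooled_ratio`,
#'   `ci_ratio`, `p`, `weights_pct` (named, summing to 100), `k`, and the
#'   `heterogeneity()` fields when `k >= 2`.
#' @export
pool_fixed <- function(effects, level = 0.95) {
  stopifnot(nrow(effects) >= 1)
  z <- qnorm(1 - (1 - level) / 2)
  w <- 1 / effects$se_log^2
  pooled <- sum(w * effects$effect_log) / sum(w)
  se <- 1 / sqrt(sum(w))
  res <- list(
    pooled_log = pooled,
    se_log = se,
    pooled_ratio = exp(pooled),
    ci_ratio = exp(pooled + c(-1, 1) * z * se),
    p = 2 * pnorm(-abs(pooled / se)),
    weights_pct = setNames(100 * w / sum(w), effects$label),
    k = nrow(effects),
    source = unique(effects$source)
  )
  if (nrow(effects) >= 2) res <- c(res, heterogeneity(effects, level = level))
  class(res) <- "meta_result"
  res
}

#' Heterogeneity statistics for an inverse-variance meta-analysis
#'
#' Cochran's \eqn{Q = \sum w_i (\theta_i - \hat\theta)^2} with `df = k - 1`;
#' DerSimonian-Laird \eqn{\tau^2} floored at zero with a Q-profile
#' confidence interval; \eqn{I^2 = \max(0, (Q - df)/Q) \cdot 100} and
#' \eqn{H = \sqrt{Q/df}} with Higgins-Thompson test-based intervals.
#'
#' @param effects A `study_effects()` tibble with at least 2 rows.
#' @param level Confidence level.
#' @return List with `Q`, `df`, `p_Q`, `tau2`, `tau2_ci`, `I2_pct`,
#'   `I2_ci_pct`, `H`, `H_ci`.
#' @export
heterogeneity <- function(effects, level = 0.95) {
  k <- nrow(effects)
  stopifnot(k >= 2)
  w <- 1 / effects$se_log^2
  theta <- effects$effect_log
  pooled <- sum(w * theta) / sum(w)
  Q <- sum(w * (theta - pooled)^2)
  df <- k - 1
  tau2 <- max(0, (Q - df) / (sum(w) - sum(w^2) / sum(w)))
  H <- sqrt(Q / df)
  I2 <- max(0, (Q - df) / Q) * 100
  if (Q == 0) I2 <- 0

  # Higgins-Thompson test-based CI for ln(H); H floored at 1.
  se_lnH <- if (Q > k) {
    0.5 * (log(Q) - log(df)) / (sqrt(2 * Q) - sqrt(2 * k - 3))
  } else if (k > 2) {
    sqrt(1 / (2 * (k - 2)) * (1 - 1 / (3 * (k - 2)^2)))
  } else {
    NA_real_
  }
  z <- qnorm(1 - (1 - level) / 2)
  H_ci <- if (is.na(se_lnH)) c(NA_real_, NA_real_) else {
    pmax(1, exp(log(max(H, 1)) + c(-1, 1) * z * se_lnH))
  }
  I2_from_H <- function(h) pmax(0, (h^2 - 1) / h^2) * 100
  I2_ci <- I2_from_H(H_ci)

  list(
    Q = Q, df = df, p_Q = pchisq(Q, df, lower.tail = FALSE),
    tau2 = tau2, tau2_ci = tau2_qprofile_ci(theta, effects$se_log, level),
    I2_pct = I2, I2_ci_pct = I2_ci,
    H = max(H, 1), H_ci = H_ci
  )
}

#' Heterogeneity indices from a printed Q statistic
#'
#' Recomputes \eqn{I^2 = \max(0, (Q - df)/Q) \cdot 100} and
#' \eqn{H = \sqrt{Q/df}} from an already-reported Cochran's Q, e.g. to
#' verify published heterogeneity summaries.
#'
#' @param Q Cochran's Q.
#' @param df Degrees of freedom (`k - 1`).
#' @return List with `I2_pct` and `H`.
#' @export
het_from_q <- function(Q, df) {
  stopifnot(Q >= 0, df >= 1)
  list(I2_pct = max(0, (Q - df) / Q) * 100, H = sqrt(Q / df))
}

# Q-profile confidence interval for tau2: the generalized Q statistic
# Q(t) = sum((theta - mu(t))^2 / (se^2 + t)) is decreasing in t; the CI is
# the set of t where Q(t) lies between the chi-square df quantiles.
tau2_qprofile_ci <- function(theta, se, level = 0.95) {
  df <- length(theta) - 1
  qgen <- function(t) {
    wi <- 1 / (se^2 + t)
    mu <- sum(wi * theta) / sum(wi)
    sum(wi * (theta - mu)^2)
  }
  lo_q <- qchisq(1 - (1 - level) / 2, df)  # Q(t) = upper quantile -> lower bound
  hi_q <- qchisq((1 - level) / 2, df)
  upper_lim <- 1000 * (max(se)^2 + var(theta))
  root <- function(target) {
    if (qgen(0) <= target) return(0)
    if (qgen(upper_lim) >= target) return(Inf)
    uniroot(function(t) qgen(t) - target, c(0, upper_lim), tol = 1e-10)$root
  }
  c(root(lo_q), root(hi_q))
}

#' @export
print.meta_result <- function(x, ...) {
  cat(sprintf("Fixed-effect inverse-variance pooling of %d studies (%s SEs)\n",
              x$k, paste(x$source, collapse = "/")))
  cat(sprintf("  pooled ratio %.3f (95%% CI %.3f-%.3f), p = %.3g\n",
              x$pooled_ratio, x$ci_ratio[1], x$ci_ratio[2], x$p))
  wt <- paste(sprintf("%s %.1f%%", names(x$weights_pct), x$weights_pct),
              collapse = ", ")
  cat("  weights:", wt, "\n")
  if (!is.null(x$Q)) {
    cat(sprintf("  Q = %.2f (df = %d, p = %.2f); tau2 = %.4f; I2 = %.1f%%; H = %.2f\n",
                x$Q, x$df, x$p_Q, x$tau2, x$I2_pct, x$H))
  }
  invisible(x)
}

#' Plain-text forest table for a pooled result
#'
#' @param effects The `study_effects()` tibble that was pooled.
#' @param result The corresponding `meta_result`.
#' @return Character vector of report lines (also printed invisibly usable
#'   with `writeLines()`).
#' @export
forest_table <- function(effects, result) {
  z <- Z95
  lines <- c(
    sprintf("%-28s %8s %8s %8s %8s", "study", "ratio", "lo95", "hi95", "weight%"),
    sprintf("%-28s %8.3f %8.3f %8.3f %8.1f",
            effects$label,
            exp(effects$effect_log),
            exp(effects$effect_log - z * effects$se_log),
            exp(effects$effect_log + z * effects$se_log),
            result$weights_pct[effects$label]),
    sprintf("%-28s %8.3f %8.3f %8.3f %8s", "pooled (fixed)",
            result$pooled_ratio, result$ci_ratio[1], result$ci_ratio[2], "100.0")
  )
  if (!is.null(result$Q)) {
    lines <- c(lines, sprintf("Q = %.3f, df = %d, p = %.3f; tau2 = %.4f; I2 = %.1f%%; H = %.3f",
                              result$Q, result$df, result$p_Q, result$tau2,
                              result$I2_pct, result$H))
  }
  lines
}
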