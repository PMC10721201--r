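#' Specify a mixed-effects model for the decision-rule battery
#'
#' A light container pinning the response, distribution family, fixed
#' effects (interactions written `a:b` or `a*b`), optional exposure offset
#' and random intercepts. The same specification is used for the dyadic
#' count models (Poisson / negative binomial with both dyad members as
#' random intercepts), the likelihood-of-allonursing logistic models, the
#' RAFI-count response models, the generalized-reciprocity totals model
#' (with a log observation-days offset) and the Gaussian latency model.
#'
#' @param response Response column name.
#' @param family One of `"poisson"`, `"nb"` (negative binomial),
#'   `"binomial"`, `"gaussian"`.
#' @param fixed Character vector of fixed-effect terms.
#' @param offset Optional column name whose log is used as exposure offset
#'   (count families only).
#' @param random Character vector of random-intercept grouping columns.
#' @return An `allonurse_model_spec`.
#' @export
model_spec <- function(response, family = c("poisson", "nb", "binomial", "gaussian"),
                       fixed = character(), offset = NULL, random = character()) {
  family <- match.arg(family)
  if (!is.null(offset) && !family %in% c("poisson", "nb")) {
    stop("an exposure offset is only meaningful for count families")
  }
  structure(list(response = response, family = family, fixed = fixed,
                 offset = offset, random = random),
            class = "allonurse_model_spec")
}

spec_formula <- function(spec) {
  rhs <- if (length(spec$fixed) > 0) paste(spec$fixed, collapse = " + ") else "1"
  if (!is.null(spec$offset)) rhs <- paste0(rhs, " + offset(log(", spec$offset, "))")
  if (length(spec$random) > 0) {
    rhs <- paste(rhs, paste(sprintf("(1 | %s)", spec$random), collapse = " + "),
                 sep = " + ")
  }
  as.formula(paste(spec$response, "~", rhs))
}

#' Fit a model specification
#'
#' Dispatches to the appropriate maximum-likelihood engine: Laplace
#' approximation (`lme4::glmer` / `lme4::glmer.nb`) for generalized mixed
#' models, REML with Satterthwaite degrees of freedom
#' (`lmerTest::lmer`) for Gaussian mixed models, and `glm` / `MASS::glm.nb`
#' / `lm` when no random intercepts are requested. When all random
#' variances collapse to (numerically) zero the mixed fit coincides with
#' the corresponding fixed-effects-only fit. Convergence problems are
#' recorded on the returned object, never silently dropped.
#'
#' @param spec An [model_spec()].
#' @param data Data frame with all referenced columns.
#' @param compute_r2 Compute the Nakagawa conditional R-squared (involves a
#'   null-model fit; disable inside tight simulation loops).
#' @return An `allonurse_fit`: the fitted model plus a coefficient table
#'   (`term`, `estimate`, `se`, `statistic`, `p`), exponentiated effects
#'   with 95% Wald CIs for log/logit links, random-intercept variances,
#'   conditional R-squared, Pearson dispersion and a `converged` flag.
#' @export
fit_glmm <- function(spec, data, compute_r2 = TRUE) {
  stopifnot(inherits(spec, "allonurse_model_spec"))
  used <- c(spec$response, all.vars(spec_formula(spec)))
  missing_cols <- setdiff(unique(used), names(data))
  if (length(missing_cols) > 0) {
    stop("data lacks columns: ", paste(missing_cols, collapse = ", "))
  }
  if (spec$family == "binomial" &&
      !all(data[[spec$response]] %in% c(0, 1))) {
    stop("binomial response must be coded 0/1")
  }
  for (g in spec$random) {
    if (length(unique(data[[g]])) < 2) {
      stop("random grouping factor '", g, "' has fewer than 2 levels")
    }
  }
  fml <- spec_formula(spec)
  msgs <- character()
  collect <- function(expr) {
    withCallingHandlers(expr,
      warning = function(w) {
        msgs <<- c(msgs, conditionMessage(w)); invokeRestart("muffleWarning")
      },
      message = function(m) {
        msgs <<- c(msgs, conditionMessage(m)); invokeRestart("muffleMessage")
      })
  }
  mixed <- length(spec$random) > 0
  model <- collect(switch(spec$family,
    poisson = if (mixed) lme4::glmer(fml, data, family = stats::poisson())
              else glm(fml, data = data, family = stats::poisson()),
    nb = if (mixed) lme4::glmer.nb(fml, data)
         else MASS::glm.nb(fml, data = data),
    binomial = if (mixed) lme4::glmer(fml, data, family = stats::binomial())
               else glm(fml, data = data, family = stats::binomial()),
    gaussian = if (mixed) lmerTest::lmer(fml, data)
               else stats::lm(fml, data = data)
  ))
  converged <- !any(grepl("failed to converge|unable to evaluate|degenerate",
                          msgs, ignore.case = TRUE))
  # embed the data in the recorded call so case-deletion refits
  # (influence) can re-evaluate it outside this frame
  if (isS4(model)) model@call$data <- data else model$call$data <- data

  co <- coef_table(model, spec$family)
  expo <- NULL
  if (spec$family != "gaussian") {
    expo <- tibble::tibble(
      term = co$term,
      ratio = exp(co$estimate),
      ci_low = exp(co$estimate - Z95 * co$se),
      ci_high = exp(co$estimate + Z95 * co$se)
    )
  }
  rv <- random_variances(model)
  disp <- if (spec$family %in% c("poisson", "nb", "binomial")) {
    pearson_dispersion(model)
  } else NA_real_

  fit <- structure(list(
    model = model, spec = spec, formula = fml, family = spec$family,
    coefficients = co, exponentiated = expo, random_variances = rv,
    conditional_r2 = NA_real_, dispersion = disp, converged = converged,
    messages = msgs, n = nobs_of(model), data = data
  ), class = "allonurse_fit")
  if (compute_r2 && converged) {
    fit$conditional_r2 <- tryCatch(conditional_r2(fit), error = function(e) NA_real_)
  }
  fit
}

nobs_of <- function(model) tryCatch(stats::nobs(model), error = function(e) NA_integer_)

coef_table <- function(model, family) {
  co <- coef_table_raw(model, family)
  co[-1] <- lapply(co[-1], unname)
  co
}

coef_table_raw <- function(model, family) {
  s <- summary(model)
  cm <- s$coefficients
  if (inherits(model, "merMod") || inherits(model, "lmerModLmerTest")) {
    if (family == "gaussian") {
      # lmerTest: Estimate, SE, df, t, p (Satterthwaite)
      tibble::tibble(term = rownames(cm), estimate = cm[, "Estimate"],
                     se = cm[, "Std. Error"], statistic = cm[, "t value"],
                     p = cm[, "Pr(>|t|)"])
    } else {
      tibble::tibble(term = rownames(cm), estimate = cm[, "Estimate"],
                     se = cm[, "Std. Error"], statistic = cm[, "z value"],
                     p = cm[, "Pr(>|z|)"])
    }
  } else {
    pcol <- grep("^Pr", colnames(cm), value = TRUE)
    stat <- setdiff(colnames(cm), c("Estimate", "Std. Error", pcol))[1]
    tibble::tibble(term = rownames(cm), estimate = cm[, "Estimate"],
                   se = cm[, "Std. Error"], statistic = cm[, stat],
                   p = cm[, pcol])
  }
}

random_variances <- function(model) {
  if (!(inherits(model, "merMod") || inherits(model, "lmerModLmerTest"))) {
    return(setNames(numeric(0), character(0)))
  }
  vc <- lme4::VarCorr(model)
  setNames(vapply(vc, function(v) v[1, 1], numeric(1)), names(vc))
}

pearson_dispersion <- function(model) {
  pr <- residuals(model, type = "pearson")
  rdf <- if (inherits(model, "merMod")) {
    nobs_of(model) - length(lme4::fixef(model)) - length(random_variances(model))
  } else {
    df.residual(model)
  }
  sum(pr^2) / rdf
}

#' Pearson overdispersion check
#'
#' Compares the Pearson chi-square over residual degrees of freedom to a
#' threshold (default 1.5). A flagged count model should be refitted with a
#' negative binomial distribution.
#'
#' @param fit An `allonurse_fit` from a count family.
#' @param threshold Dispersion ratio above which the fit is flagged.
#' @return List with `ratio`, `threshold`, `overdispersed`.
#' @export
check_overdispersion <- function(fit, threshold = 1.5) {
  if (!fit$family %in% c("poisson", "nb")) {
    stop("overdispersion check applies to count families")
  }
  ratio <- fit$dispersion
  list(ratio = ratio, threshold = threshold,
       overdispersed = is.finite(ratio) && ratio > threshold)
}

#' Variance inflation factors of a fixed-effects design
#'
#' Standard \eqn{VIF_j = 1/(1 - R^2_j)} where \eqn{R^2_j} is from the
#' regression of term `j`'s design column on all other non-intercept
#' columns. Values of 5 or more are flagged as evidence of
#' multicollinearity; a perfectly collinear column yields `Inf`, not an
#' error.
#'
#' @param x An `allonurse_fit`, a fitted model, or a numeric design matrix
#'   (intercept column dropped automatically if present).
#' @param flag_at Flag threshold (default 5).
#' @return Tibble `term`, `vif`, `flagged`.
#' @export
vif_terms <- function(x, flag_at = 5) {
  X <- if (inherits(x, "allonurse_fit")) model.matrix(x$model)
       else if (is.matrix(x)) x
       else model.matrix(x)
  icpt <- which(apply(X, 2, function(col) all(col == col[1])))
  if (length(icpt) > 0) X <- X[, -icpt, drop = FALSE]
  if (ncol(X) < 2) stop("VIF needs at least 2 non-intercept terms")
  vifs <- vapply(seq_len(ncol(X)), function(j) {
    y <- X[, j]
    Z <- cbind(1, X[, -j, drop = FALSE])
    f <- stats::lm.fit(Z, y)
    rss <- sum(f$residuals^2)
    tss <- sum((y - mean(y))^2)
    r2 <- 1 - rss / tss
    if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
  }, numeric(1))
  tibble::tibble(term = colnames(X), vif = vifs, flagged = vifs >= flag_at)
}

#' Flag outliers by absolute z-score
#'
#' @param x Numeric vector.
#' @param cutoff Absolute z-score above which a value is flagged
#'   (default 3.3).
#' @return Logical flags, same length as `x`.
#' @export
zscore_outliers <- function(x, cutoff = 3.3) {
  s <- sd(x, na.rm = TRUE)
  if (!is.finite(s) || s == 0) {
    warning("constant (or degenerate) vector: no outliers can be flagged")
    return(rep(FALSE, length(x)))
  }
  z <- (x - mean(x, na.rm = TRUE)) / s
  !is.na(z) & abs(z) > cutoff
}

#' Influence cutoffs from the number of mothers
#'
#' dfbetas cutoff `2/sqrt(N)` and Cook's distance cutoff `4/N`, with N the
#' number of mothers in the group (N = 25 gives 0.40 and 0.16; N = 8 gives
#' 0.71 and 0.50 at the reported rounding).
#'
#' @param n_mothers Number of mothers.
#' @return Named numeric vector `dfbetas`, `cooks`.
#' @export
influence_cutoffs <- function(n_mothers) {
  stopifnot(n_mothers >= 2)
  c(dfbetas = 2 / sqrt(n_mothers), cooks = 4 / n_mothers)
}

#' Case-deletion influence diagnostics
#'
#' Exact leave-one-observation-out dfbetas and Cook's distances (refitting
#' for mixed models), flagged at `2/sqrt(N)` and `4/N` with N the number
#' of mothers.
#'
#' @param fit An `allonurse_fit`.
#' @param n_mothers Number of mothers in the group, used for the cutoffs.
#' @return List: `dfbetas` (matrix), `cooks` (vector), `cutoffs`,
#'   `dfbetas_flags` (per-observation any-term flag), `cooks_flags`.
#' @export
influence_measures <- function(fit, n_mothers) {
  cuts <- influence_cutoffs(n_mothers)
  model <- fit$model
  if (inherits(model, "merMod") || inherits(model, "lmerModLmerTest")) {
    inf <- suppressWarnings(stats::influence(model, do.coef = TRUE))
    dfb <- stats::dfbetas(inf)
    cd <- stats::cooks.distance(inf)
  } else {
    dfb <- stats::dfbetas(model)
    cd <- stats::cooks.distance(model)
  }
  list(
    dfbetas = dfb, cooks = cd, cutoffs = cuts,
    dfbetas_flags = apply(abs(dfb) > cuts["dfbetas"], 1, any),
    cooks_flags = cd > cuts["cooks"]
  )
}

#' Expected count from a log-link linear predictor
#'
#' Evaluates `exp(intercept + sum(beta * x))` at the stated covariate
#' values, with all unmentioned terms at their reference/zero.
#'
#' @param object An `allonurse_fit` or a named coefficient vector (must
#'   include `"(Intercept)"`).
#' @param at Named list/vector of covariate values.
#' @return Expected count on the response scale.
#' @examples
#' predict_rate(c("(Intercept)" = 0.91, received = 0.05), c(received = 10))
#' @export
predict_rate <- function(object, at = c()) {
  beta <- if (inherits(object, "allonurse_fit")) {
    setNames(object$coefficients$estimate, object$coefficients$term)
  } else {
    object
  }
  if (!"(Intercept)" %in% names(beta)) stop("missing intercept coefficient")
  at <- unlist(at)
  eta <- beta[["(Intercept)"]]
  for (nm in names(at)) {
    if (!nm %in% names(beta)) stop("missing coefficient for term '", nm, "'")
    eta <- eta + beta[[nm]] * at[[nm]]
  }
  unname(exp(eta))
}

#' Nakagawa conditional R-squared
#'
#' Variance-partition conditional R-squared: the proportion of total
#' latent-scale variance attributable to fixed plus random effects,
#' \deqn{R^2_c = (\sigma^2_f + \sigma^2_r) / (\sigma^2_f + \sigma^2_r + \sigma^2_e)}
#' with distribution-specific residual variance \eqn{\sigma^2_e}: the
#' residual variance for Gaussian fits, \eqn{\pi^2/3} for the logit link,
#' and the trigamma approximation \eqn{\psi_1(\lambda)} for Poisson
#' (\eqn{\psi_1((1/\lambda + 1/\theta)^{-1})} for negative binomial), with
#' \eqn{\lambda} taken from an intercept-plus-random-effects null model.
#'
#' @param fit An `allonurse_fit`.
#' @return Conditional R-squared in `[0, 1]`.
#' @export
conditional_r2 <- function(fit) {
  if (!fit$converged) stop("conditional R-squared is undefined for unconverged fits")
  model <- fit$model
  beta <- if (inherits(model, "merMod") || inherits(model, "lmerModLmerTest")) {
    lme4::fixef(model)
  } else coef(model)
  X <- model.matrix(model)
  var_f <- var(as.vector(X %*% beta))
  var_r <- sum(fit$random_variances)
  var_e <- switch(fit$family,
    gaussian = stats::sigma(model)^2,
    binomial = pi^2 / 3,
    poisson = trigamma(null_lambda(fit)),
    nb = {
      theta <- nb_theta(model)
      trigamma(1 / (1 / null_lambda(fit) + 1 / theta))
    })
  r2 <- (var_f + var_r) / (var_f + var_r + var_e)
  min(max(r2, 0), 1)
}

nb_theta <- function(model) {
  if (inherits(model, "merMod")) lme4::getME(model, "glmer.nb.theta")
  else model$theta
}

# Latent-scale expected count from the null (intercept + random effects +
# offset) model, used by the trigamma residual-variance approximation.
null_lambda <- function(fit) {
  spec <- fit$spec
  null_spec <- model_spec(spec$response, family = if (spec$family == "nb") "poisson" else spec$family,
                          fixed = character(), offset = spec$offset,
                          random = spec$random)
  nf <- suppressWarnings(suppressMessages(fit_glmm(null_spec, fit$data,
                                                   compute_r2 = FALSE)))
  b0 <- nf$coefficients$estimate[nf$coefficients$term == "(Intercept)"]
  exp(b0 + 0.5 * sum(nf$random_variances))
}

#' @export
print.allonurse_fit <- function(x, ...) {
  cat(sprintf("allonurse_fit: %s, %s\n", x$family, deparse(x$formula)))
  cat(sprintf("n = %d, converged = %s, dispersion = %s, conditional R2 = %s\n",
              x$n, x$converged,
              ifelse(is.na(x$dispersion), "NA", sprintf("%.2f", x$dispersion)),
              ifelse(is.na(x$conditional_r2), "NA", sprintf("%.2f", x$conditional_r2))))
  print(as.data.frame(x$coefficients), row.names = FALSE)
  if (!is.null(x$exponentiated)) {
    cat("exponentiated effects (ratio, 95% CI):\n")
    print(as.data.frame(x$exponentiated), row.names = FALSE)
  }
  if (length(x$random_variances) > 0) {
    cat("random-intercept variances:\n")
    print(x$random_variances)
  }
  invisible(x)
}

#' Serializable summary of a fit
#'
#' Drops the fitted-model object and data, keeping the plain-number
#' summaries that round-trip through JSON.
#'
#' @param fit An `allonurse_fit`.
#' @return Plain list: family, formula, coefficients, exponentiated,
#'   random_variances, conditional_r2, dispersion, converged, n.
#' @export
tidy_fit <- function(fit) {
  list(
    family = fit$family,
    formula = paste(deparse(fit$formula), collapse = " "),
    coefficients = as.data.frame(fit$coefficients),
    exponentiated = if (is.null(fit$exponentiated)) NULL else as.data.frame(fit$exponentiated),
    random_variances = as.list(fit$random_variances),
    conditional_r2 = fit$conditional_r2,
    dispersion = fit$dispersion,
    converged = fit$converged,
    n = fit$n
  )
}
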