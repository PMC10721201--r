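# Shared simulated dyad-like Poisson dataset with known parameters.
sim_poisson_data <- function(n = 300, beta0 = 0.9, beta1 = 0.05,
                             re_sd = 0.5, n_groups = 25, seed = 101) {
  set.seed(seed)
  g <- sample(paste0("g", seq_len(n_groups)), n, replace = TRUE)
  u <- setNames(rnorm(n_groups, 0, re_sd), paste0("g", seq_len(n_groups)))
  x <- rpois(n, 8)
  eta <- beta0 + beta1 * x + u[g]
  data.frame(y = rpois(n, exp(eta)), x = x, g = g)
}

test_that("the Poisson mixed fit recovers known parameters within Monte-Carlo error", {
  d <- sim_poisson_data()
  fit <- fit_glmm(model_spec("y", "poisson", "x", random = "g"), d)
  cf <- fit$coefficients
  b1 <- cf[cf$term == "x", ]
  expect_lt(abs(b1$estimate - 0.05), 3 * b1$se)
  expect_true(fit$converged)
  expect_gt(fit$random_variances[["g"]], 0.05)
  expect_lt(fit$random_variances[["g"]], 0.8)
  # exponentiated effects are exp of the log-scale CI bounds (1e-9 contract)
  ex <- fit$exponentiated[fit$exponentiated$term == "x", ]
  expect_equal(ex$ratio, exp(b1$estimate), tolerance = 1e-9)
  expect_equal(ex$ci_low, exp(b1$estimate - 1.959964 * b1$se), tolerance = 1e-9)
  expect_equal(ex$ci_high, exp(b1$estimate + 1.959964 * b1$se), tolerance = 1e-9)
})

test_that("zero random variance degenerates to the fixed-effects fit", {
  set.seed(102)
  # no group structure at all: the mixed fit must collapse onto glm
  d <- data.frame(x = rnorm(200), g = sample(letters[1:10], 200, replace = TRUE))
  d$y <- rpois(200, exp(0.5 + 0.3 * d$x))
  mixed <- suppressMessages(fit_glmm(model_spec("y", "poisson", "x", random = "g"), d))
  plain <- glm(y ~ x, data = d, family = poisson)
  expect_lt(sum(mixed$random_variances), 1e-8)
  expect_equal(unname(setNames(mixed$coefficients$estimate,
                               mixed$coefficients$term)[c("(Intercept)", "x")]),
               unname(coef(plain)), tolerance = 1e-4)
  # binomial flavour of the same contract
  d$z <- rbinom(200, 1, plogis(0.2 + 0.5 * d$x))
  mixed_b <- suppressMessages(fit_glmm(model_spec("z", "binomial", "x", random = "g"), d))
  plain_b <- glm(z ~ x, data = d, family = binomial)
  expect_equal(unname(setNames(mixed_b$coefficients$estimate,
                               mixed_b$coefficients$term)[c("(Intercept)", "x")]),
               unname(coef(plain_b)), tolerance = 1e-4)
})

test_that("95% CI coverage is near nominal across simulated Poisson and Gaussian fits", {
  covered_p <- 0; covered_g <- 0; n_rep <- 60
  for (i in seq_len(n_rep)) {
    d <- sim_poisson_data(n = 150, n_groups = 15, seed = 200 + i)
    fit <- suppressMessages(fit_glmm(model_spec("y", "poisson", "x", random = "g"),
                                     d, compute_r2 = FALSE))
    b <- fit$coefficients[fit$coefficients$term == "x", ]
    covered_p <- covered_p + (abs(b$estimate - 0.05) <= 1.959964 * b$se)

    set.seed(300 + i)
    dg <- data.frame(x = rnorm(120), g = rep(letters[1:12], 10))
    dg$y <- 1 + 0.5 * dg$x + rnorm(12, 0, 0.5)[match(dg$g, letters[1:12])] + rnorm(120)
    fg <- suppressMessages(fit_glmm(model_spec("y", "gaussian", "x", random = "g"),
                                    dg, compute_r2 = FALSE))
    bg <- fg$coefficients[fg$coefficients$term == "x", ]
    covered_g <- covered_g + (abs(bg$estimate - 0.5) <= 1.959964 * bg$se)
  }
  expect_gte(covered_p / n_rep, 0.87)
  expect_lte(covered_p / n_rep, 1)
  expect_gte(covered_g / n_rep, 0.87)
})

test_that("doubling exposures and counts leaves offset-model rate coefficients invariant", {
  set.seed(103)
  d <- data.frame(x = rpois(200, 5), g = sample(letters[1:10], 200, replace = TRUE),
                  days = sample(c(25, 65), 200, replace = TRUE))
  d$y <- rpois(200, d$days * exp(-2 + 0.1 * d$x))
  f1 <- suppressMessages(fit_glmm(model_spec("y", "poisson", "x", offset = "days",
                                             random = "g"), d, compute_r2 = FALSE))
  d2 <- d; d2$days <- 2 * d$days; d2$y <- 2 * d$y
  f2 <- suppressMessages(fit_glmm(model_spec("y", "poisson", "x", offset = "days",
                                             random = "g"), d2, compute_r2 = FALSE))
  expect_equal(f1$coefficients$estimate[f1$coefficients$term == "x"],
               f2$coefficients$estimate[f2$coefficients$term == "x"],
               tolerance = 1e-3)
})

test_that("overdispersion is flagged on negative-binomial data but rarely on Poisson data", {
  flag_pois <- 0; flag_nb <- 0; n_rep <- 40
  for (i in seq_len(n_rep)) {
    set.seed(400 + i)
    g <- rep(letters[1:10], 15)
    x <- rnorm(150)
    mu <- exp(1 + 0.2 * x)
    d_pois <- data.frame(y = rpois(150, mu), x = x, g = g)
    d_nb <- data.frame(y = rnbinom(150, size = mu, mu = mu), x = x, g = g)  # var = 2 mu
    fp <- suppressMessages(fit_glmm(model_spec("y", "poisson", "x", random = "g"),
                                    d_pois, compute_r2 = FALSE))
    fn <- suppressMessages(fit_glmm(model_spec("y", "poisson", "x", random = "g"),
                                    d_nb, compute_r2 = FALSE))
    flag_pois <- flag_pois + check_overdispersion(fp)$overdispersed
    flag_nb <- flag_nb + check_overdispersion(fn)$overdispersed
  }
  expect_lte(flag_pois / n_rep, 0.10)
  expect_gte(flag_nb / n_rep, 0.90)
  # a ratio of exactly 1 is never flagged
  expect_false(check_overdispersion(structure(list(family = "poisson",
                                                   dispersion = 1.0),
                                              class = "allonurse_fit"))$overdispersed)
})

test_that("VIF is 1 for orthogonal predictors, infinite under perfect collinearity, and matches car", {
  X <- cbind(a = rep(c(-1, 1), 50), b = rep(c(-1, 1), each = 50))
  v <- vif_terms(X)
  expect_equal(v$vif, c(1, 1), tolerance = 1e-10)
  expect_false(any(v$flagged))

  X2 <- cbind(x = rnorm(100))
  X2 <- cbind(X2, y = 2 * X2[, "x"])
  expect_equal(vif_terms(X2)$vif, c(Inf, Inf))

  # x and x*r with little variation in r inflate VIF, as in the interaction models
  set.seed(104)
  x <- rpois(100, 8); r <- rnorm(100, 0, 0.05)
  X3 <- cbind(x = x, r = r, xr = x * r)
  d <- data.frame(y = rnorm(100), x = x, r = r)
  expect_gt(max(vif_terms(X3)$vif), 5)
  skip_if_not_installed("car")
  m <- lm(y ~ x + r + x:r, data = d)
  expect_equal(vif_terms(m)$vif, unname(car::vif(m)), tolerance = 1e-8)
})

test_that("z-score outlier flags match the 3.3 rule", {
  set.seed(105)
  x <- rnorm(1000)
  expect_lt(mean(zscore_outliers(x)), 0.01)  # tail mass beyond 3.3 is ~0.1%
  y <- c(rnorm(50), 100)
  flags <- zscore_outliers(y)
  # a constant vector warns and flags nothing
  expect_warning(f0 <- zscore_outliers(rep(2, 10)), "constant")
  expect_false(any(f0))
  x10 <- c(rnorm(100), 10 * sd(rnorm(100)))
  z <- c(rep(0, 100), 10)
  expect_equal(which(zscore_outliers(z)), 101L)
})

test_that("influence cutoffs reproduce the group-size values and clean data is unflagged", {
  expect_equal(unname(influence_cutoffs(25)), c(0.40, 0.16))
  expect_equal(unname(influence_cutoffs(8)), c(2 / sqrt(8), 0.50))
  expect_equal(round(influence_cutoffs(8)[["dfbetas"]], 2), 0.71)

  set.seed(106)
  d <- data.frame(x = rnorm(60), g = rep(letters[1:6], 10))
  d$y <- rpois(60, exp(0.6 + 0.2 * d$x))
  fit <- suppressMessages(fit_glmm(model_spec("y", "poisson", "x", random = "g"), d))
  inf <- influence_measures(fit, n_mothers = 25)
  expect_length(inf$cooks_flags, 60)
  expect_lte(mean(inf$cooks_flags), 0.15)  # balanced data: hardly any flags
})

test_that("expected counts from printed coefficients reproduce the worked rates", {
  cf <- c("(Intercept)" = 0.91, received = 0.05)
  expect_equal(round(predict_rate(cf, c(received = 10)), 2), 4.10)
  cf2 <- c("(Intercept)" = 0.82, received = 0.09)
  expect_equal(round(predict_rate(cf2, c(received = 15)), 2), 8.76)
  expect_equal(predict_rate(c("(Intercept)" = 1.3), c()), exp(1.3))
  expect_error(predict_rate(cf, c(unknown = 1)), "missing coefficient")
})

test_that("conditional R2 matches the Gaussian decomposition and grows with effect size", {
  set.seed(107)
  d <- data.frame(x = rnorm(200), g = rep(letters[1:20], 10))
  u <- rnorm(20, 0, 1)
  d$y <- 2 + 1.5 * d$x + u[match(d$g, letters[1:20])] + rnorm(200, 0, 0.7)
  fit <- fit_glmm(model_spec("y", "gaussian", "x", random = "g"), d)
  # closed-form check: (var_f + var_r) / (var_f + var_r + sigma^2)
  vf <- var(lme4::fixef(fit$model)[["x"]] * d$x)
  vr <- sum(fit$random_variances)
  s2 <- sigma(fit$model)^2
  expect_equal(fit$conditional_r2, (vf + vr) / (vf + vr + s2), tolerance = 1e-6)
  expect_gt(fit$conditional_r2, 0.5)

  # near-zero R2 when there is neither fixed nor random signal
  set.seed(108)
  d0 <- data.frame(x = rnorm(300), g = rep(letters[1:10], 30))
  d0$y <- rpois(300, exp(1))
  f0 <- suppressMessages(fit_glmm(model_spec("y", "poisson", "x", random = "g"), d0))
  expect_lt(f0$conditional_r2, 0.1)

  # monotone in the fixed-effect size across three settings
  r2s <- sapply(c(0.05, 0.2, 0.5), function(b) {
    set.seed(109)
    dd <- data.frame(x = rnorm(300), g = rep(letters[1:10], 30))
    dd$y <- rpois(300, exp(1 + b * dd$x + 0.3 * rnorm(10)[match(dd$g, letters[1:10])]))
    suppressMessages(fit_glmm(model_spec("y", "poisson", "x", random = "g"),
                              dd))$conditional_r2
  })
  expect_true(all(diff(r2s) > 0))
})

test_that("model specification guards its invariants", {
  expect_error(model_spec("y", "binomial", "x", offset = "days"),
               "count families")
  d <- data.frame(y = c(0, 1, 2), x = 1:3, g = c("a", "b", "a"))
  expect_error(fit_glmm(model_spec("y", "binomial", "x", random = "g"), d),
               "0/1")
  expect_error(fit_glmm(model_spec("y", "poisson", "x", random = "h"), d),
               "lacks columns")
  d$h <- "same"
  expect_error(fit_glmm(model_spec("y", "poisson", "x", random = "h"), d),
               "fewer than 2 levels")
})
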