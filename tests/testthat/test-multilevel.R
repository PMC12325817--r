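test_that("log transform handles offsets, zeros and skewness", {
  expect_equal(log_transform_outcome(exp(1), offset = 0), 1)
  expect_equal(log_transform_outcome(0), 0)
  expect_error(log_transform_outcome(-1), ">= 0")
  expect_error(log_transform_outcome(0, offset = 0), "offset")

  set.seed(10)
  y <- stats::rlnorm(5000, 6, 1)
  skew <- function(x) mean((x - mean(x))^3) / stats::sd(x)^3
  expect_lt(abs(skew(log_transform_outcome(y, offset = 0))), abs(skew(y)))
})

test_that("logistic transform is a symmetric probability map", {
  expect_equal(predicted_probability(0), 0.5)
  expect_equal(predicted_probability(log(3)), 0.75)
  set.seed(2)
  x <- stats::rnorm(50, 0, 3)
  expect_equal(predicted_probability(x) + predicted_probability(-x),
               rep(1, 50))
  expect_error(predicted_probability(Inf), "finite")
})

test_that("ICC follows the variance-ratio formula with the logistic constant", {
  expect_equal(icc(1, 3)$icc, 0.25)
  expect_equal(icc(0, 17)$icc, 0)
  expect_equal(icc(pi^2 / 3, "binary")$icc, 0.5)
  expect_equal(icc(1, "binary")$level1, pi^2 / 3)
  expect_error(icc(-0.1, 1), ">= 0")
  expect_error(icc(1, 0), "level-1")
  # monotone in tau^2 at fixed level-1 variance
  vals <- sapply(seq(0, 3, by = 0.25), function(t2) icc(t2, 1.7)$icc)
  expect_true(all(diff(vals) > 0))
})

test_that("REML components on a balanced design match ANOVA method of moments", {
  panel <- balanced_panel(J = 30L, m = 40L, tau = 0.5, sigma = 1, seed = 7L)
  fit <- fit_random_intercept(panel, "cost", group_col = "popgroup_id",
                              log_offset = 0)
  # independent oracle: one-way ANOVA mean squares
  y <- log(panel$cost)
  a <- stats::aov(y ~ factor(panel$region_id))
  ms <- summary(a)[[1L]][["Mean Sq"]]
  m <- 40L
  tau2_mom <- (ms[1L] - ms[2L]) / m
  expect_equal(fit$tau2, tau2_mom, tolerance = 1e-6)
  expect_equal(fit$sigma2, ms[2L], tolerance = 1e-6)
})

test_that("continuous parameter recovery on a seeded simulation", {
  spec <- simulation_spec(n_regions = 48L, n_patients = 20000L,
                          n_popgroups = 15L, seed = 19L,
                          continuous = list(tau = 0.5, sigma = 1))
  sim <- simulate_claims(spec)
  panel <- aggregate_small_popgroups(sim$panel, sim$catalog)
  fit <- fit_random_intercept(panel, "cost", log_offset = 0)
  expect_lt(abs(fit$tau2 - 0.25) / 0.25, 0.35)
  expect_lt(abs(fit$sigma2 - 1), 0.1)
  truth <- sim$truth$regions
  u <- fit$ranef$u_hat[match(truth$region_id, fit$ranef$region_id)]
  expect_gte(stats::cor(u, truth$u_continuous), 0.9)
  # regional intercept predictions average out to ~0
  expect_lt(abs(mean(fit$ranef$u_hat)), 0.05)
})

test_that("a zero-variance region level is recovered as near-zero ICC", {
  spec <- simulation_spec(n_regions = 30L, n_patients = 12000L,
                          n_popgroups = 10L, seed = 23L,
                          continuous = list(tau = 0, sigma = 1))
  sim <- simulate_claims(spec)
  panel <- aggregate_small_popgroups(sim$panel, sim$catalog)
  fit <- fit_random_intercept(panel, "cost", log_offset = 0)
  expect_lt(fit$tau2, 0.01)
  expect_lt(fit$icc$icc, 0.01)
})

test_that("empirical-Bayes predictions shrink raw region deviations", {
  panel <- balanced_panel(J = 25L, m = 20L, tau = 0.4, sigma = 1.2,
                          seed = 13L)
  fit <- fit_random_intercept(panel, "cost", group_col = "popgroup_id",
                              log_offset = 0)
  y <- log(panel$cost)
  raw <- tapply(y, panel$region_id, mean) - mean(y)
  u <- fit$ranef$u_hat[match(names(raw), fit$ranef$region_id)]
  expect_true(all(abs(u) <= abs(raw) + 1e-8))
})

test_that("covariate fit with Z identically zero reduces to the intercept fit", {
  panel <- toy_panel(n = 800L, J = 10L, K = 4L, seed = 27L)
  regions <- data.frame(region_id = sort(unique(panel$region_id)),
                        z0 = 0)
  f0 <- fit_random_intercept(panel, "cost", group_col = "popgroup_id")
  f1 <- suppressMessages(
    fit_random_slope(panel, "cost", regions, "z0",
                     group_col = "popgroup_id"))
  expect_equal(f1$gamma00, f0$gamma00, tolerance = 1e-6)
  expect_equal(f1$tau2, f0$tau2, tolerance = 1e-6)
  expect_equal(f1$group_effects, f0$group_effects, tolerance = 1e-6)
})

test_that("a known regional covariate effect is recovered", {
  spec <- simulation_spec(n_regions = 48L, n_patients = 20000L,
                          n_popgroups = 10L, seed = 29L,
                          continuous = list(tau = 0.3, sigma = 1))
  sim <- simulate_claims(spec)
  J <- spec$n_regions
  set.seed(101)
  z <- as.numeric(scale(stats::rnorm(J)))
  regions <- data.frame(region_id = sprintf("R%03d", seq_len(J)), z = z)
  df <- as.data.frame(sim$panel)
  idx <- match(df$region_id, regions$region_id)
  df$cost <- df$cost * exp(0.3 * z[idx])   # gamma10 = 0.3 on the log scale
  panel <- aggregate_small_popgroups(
    patient_panel(df, outcome_types = outcome_types(sim$panel)),
    sim$catalog)
  fit <- fit_random_slope(panel, "cost", regions, "z",
                          slope_mode = "fixed", log_offset = 0)
  est <- fit$covariate_effects[["z"]]
  se <- fit$fixef_se[["z"]]
  expect_lt(abs(est - 0.3), 3 * se)

  # a truly zero random slope is estimated near the boundary: far below
  # the variance a real regional slope heterogeneity (tau1 ~ 0.3, i.e.
  # variance 0.09) would produce
  fit_r <- fit_random_slope(panel, "cost", regions, "z",
                            slope_mode = "random", log_offset = 0)
  slope_var <- fit_r$slope_vcov["z", "z"]
  expect_lt(slope_var, 0.03)
  expect_error(
    fit_random_slope(panel, "cost",
                     data.frame(region_id = regions$region_id, z = 5),
                     "z"),
    "constant")
})

test_that("explained-variation statistics behave at the null and under signal", {
  # no group effects anywhere: both R2 near zero
  spec0 <- simulation_spec(n_regions = 20L, n_patients = 6000L,
                           n_popgroups = 6L, n_macro_groups = 3L, seed = 37L,
                           continuous = list(effect_sd = 0, tau = 0.2),
                           binary = list(effect_sd = 0, tau = 0.2))
  sim0 <- simulate_claims(spec0)
  p0 <- aggregate_small_popgroups(sim0$panel, sim0$catalog)
  fc0 <- fit_random_intercept(p0, "cost", log_offset = 0)
  expect_lt(abs(fit_statistics(fc0)$adjusted_r2), 0.01)
  fb0 <- fit_random_intercept(p0, "hospitalization")
  nag0 <- fit_statistics(fb0)$nagelkerke_r2
  expect_lt(nag0, 0.01)

  # strong group effects: Nagelkerke strictly larger than under the null
  spec1 <- simulation_spec(n_regions = 20L, n_patients = 6000L,
                           n_popgroups = 6L, n_macro_groups = 3L, seed = 37L,
                           binary = list(effect_sd = 1.5, tau = 0.2))
  sim1 <- simulate_claims(spec1)
  p1 <- aggregate_small_popgroups(sim1$panel, sim1$catalog)
  fb1 <- fit_random_intercept(p1, "hospitalization")
  expect_gt(fit_statistics(fb1)$nagelkerke_r2, nag0)
})

test_that("quadrature oracle reduces to plain logistic likelihood at tau = 0", {
  set.seed(5)
  n <- 300L
  eta <- stats::rnorm(n, -1, 0.8)
  y <- stats::rbinom(n, 1L, stats::plogis(eta))
  region <- sample(sprintf("R%d", 1:6), n, replace = TRUE)
  ll0 <- marginal_loglik_oracle(y, eta, region, tau2 = 0)
  expect_equal(ll0, sum(stats::dbinom(y, 1, stats::plogis(eta),
                                      log = TRUE)))
  # tiny tau2 approaches the same limit
  expect_equal(marginal_loglik_oracle(y, eta, region, tau2 = 1e-10), ll0,
               tolerance = 1e-6)
})

test_that("fitted optimum is a local maximum of the oracle likelihood", {
  spec <- simulation_spec(n_regions = 10L, n_patients = 600L,
                          n_popgroups = 6L, n_macro_groups = 3L, seed = 41L,
                          binary = list(tau = 0.6))
  sim <- simulate_claims(spec)
  panel <- aggregate_small_popgroups(sim$panel, sim$catalog)
  fit <- fit_random_intercept(panel, "hospitalization", nAGQ = 15L)
  y <- lme4::getME(fit$model, "y")
  eta <- stats::predict(fit$model, re.form = NA)
  region <- as.character(fit$model@frame$region_id)
  at_opt <- marginal_loglik_oracle(y, eta, region, fit$tau2)
  expect_lt(marginal_loglik_oracle(y, eta + 0.15, region, fit$tau2), at_opt)
  expect_lt(marginal_loglik_oracle(y, eta, region, fit$tau2 * 2), at_opt)
  expect_lt(marginal_loglik_oracle(y, eta, region, fit$tau2 / 2.5), at_opt)
})
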