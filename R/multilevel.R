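#' Log-transform a skewed continuous outcome
#'
#' Costs and bed-day counts are strongly right-skewed; the log-linear models
#' are fitted on the natural-log scale. Zeros are handled by a configurable
#' offset (default `log(y + 1)`); the offset used is recorded in the fit
#' metadata.
#'
#' @param values non-negative outcome values.
#' @param offset added before taking logs (default 1; `0` disables the
#'   offset, in which case zeros are rejected).
#' @return `log(values + offset)`.
#' @export
log_transform_outcome <- function(values, offset = 1) {
  if (any(is.na(values)))
    stop("missing values in outcome", call. = FALSE)
  if (any(values < 0))
    stop("continuous outcome must be >= 0", call. = FALSE)
  if (offset == 0 && any(values == 0))
    stop("zero outcome values require a positive offset", call. = FALSE)
  log(values + offset)
}

#' Logistic transform of a linear predictor
#'
#' Maps a logit-scale linear predictor to a predicted probability,
#' `exp(x) / (1 + exp(x))`.
#'
#' @param linear_predictor finite numeric values on the logit scale.
#' @return Probabilities in (0, 1).
#' @export
predicted_probability <- function(linear_predictor) {
  if (any(!is.finite(linear_predictor)))
    stop("linear predictor must be finite", call. = FALSE)
  stats::plogis(linear_predictor)
}

#' Intraclass correlation from variance components
#'
#' The share of total outcome variance attributable to the regional level,
#' `tau2 / (tau2 + level-1 variance)`. For binary (logit-link) models the
#' level-1 variance is fixed at the variance of the standard logistic
#' distribution, `pi^2/3 ~ 3.29`.
#'
#' @param tau2 regional random-intercept variance (>= 0).
#' @param level1 level-1 (residual) variance, or the string `"binary"` to
#'   use `pi^2/3`.
#' @return A `variance_decomposition` list: `tau2`, `level1`, `icc`.
#' @export
icc <- function(tau2, level1) {
  if (is.na(tau2) || tau2 < 0)
    stop("tau2 must be >= 0", call. = FALSE)
  if (identical(level1, "binary")) level1 <- pi^2 / 3
  if (!is.numeric(level1) || level1 <= 0)
    stop("level-1 variance must be > 0 (or \"binary\")", call. = FALSE)
  out <- list(tau2 = tau2, level1 = level1,
              icc = if (tau2 == 0) 0 else tau2 / (tau2 + level1))
  class(out) <- "variance_decomposition"
  out
}

#' @export
print.variance_decomposition <- function(x, ...) {
  cat(sprintf("tau^2 = %.4f, level-1 variance = %.4f, ICC = %.4f\n",
              x$tau2, x$level1, x$icc))
  invisible(x)
}

# reference level: most populated group; ties -> lexicographically smallest
.reference_group <- function(g) {
  counts <- table(g)
  cand <- names(counts)[counts == max(counts)]
  sort(cand)[1L]
}

.glmer_control <- function() {
  lme4::glmerControl(calc.derivs = FALSE, optimizer = "nloptwrap")
}

.check_convergence <- function(model) {
  conv <- model@optinfo$conv$opt
  if (!is.null(conv) && conv != 0)
    stop("mixed-model optimizer did not converge (code ", conv, "); ",
         "optimizer messages: ",
         paste(unlist(model@optinfo$message), collapse = "; "),
         call. = FALSE)
  invisible(model)
}

# shared extraction of a fitted lme4 model into a multilevel_fit
.build_fit <- function(model, null_model, data, outcome, type,
                       reference_group, log_offset, covariate_names,
                       random_slopes = character()) {
  fe <- lme4::fixef(model)
  fe_se <- sqrt(diag(as.matrix(stats::vcov(model))))
  vc <- lme4::VarCorr(model)$region_id
  tau2 <- vc[1L, 1L]
  sigma2 <- if (type == "continuous") stats::sigma(model)^2 else NA_real_
  slope_vcov <- if (length(random_slopes) > 0L) as.matrix(vc) else NULL

  re <- lme4::ranef(model, condVar = TRUE)$region_id
  pv <- attr(re, "postVar")
  ranef_df <- data.frame(region_id = rownames(re),
                         u_hat = re[["(Intercept)"]],
                         se = sqrt(pv[1L, 1L, ]),
                         stringsAsFactors = FALSE)

  # ICC components come from the unconditional means (null) model
  null_tau2 <- lme4::VarCorr(null_model)$region_id[1L, 1L]
  vd <- if (type == "continuous")
    icc(null_tau2, stats::sigma(null_model)^2)
  else
    icc(null_tau2, "binary")

  is_dummy <- grepl("^effective_group", names(fe))
  group_effects <- fe[is_dummy]
  names(group_effects) <- sub("^effective_group", "", names(group_effects))
  cov_eff <- fe[names(fe) %in% covariate_names]

  out <- list(model = model, null_model = null_model,
              outcome = outcome, type = type,
              gamma00 = unname(fe[["(Intercept)"]]),
              group_effects = group_effects,
              covariate_effects = cov_eff,
              fixef = fe, fixef_se = fe_se,
              tau2 = tau2, sigma2 = sigma2,
              null_tau2 = null_tau2,
              null_sigma2 = if (type == "continuous")
                stats::sigma(null_model)^2 else pi^2 / 3,
              slope_vcov = slope_vcov,
              random_slopes = random_slopes,
              ranef = ranef_df,
              logLik = as.numeric(stats::logLik(model)),
              null_logLik = as.numeric(stats::logLik(null_model)),
              n = nrow(data), J = nrow(ranef_df),
              reference_group = reference_group,
              log_offset = log_offset,
              icc = vd)
  class(out) <- "multilevel_fit"
  out
}

# assemble the model frame from a panel
.model_frame <- function(panel, outcome, type, group_col, log_offset) {
  if (!group_col %in% names(panel))
    stop("group column '", group_col, "' not found; run ",
         "aggregate_small_popgroups() first or pass group_col explicitly",
         call. = FALSE)
  v <- .check_outcome(panel, outcome)
  if (type == "binary" && !all(v %in% c(0, 1)))
    stop("binary outcome must be coded 0/1", call. = FALSE)
  y <- if (type == "continuous") log_transform_outcome(v, log_offset) else v
  refg <- .reference_group(panel[[group_col]])
  data.frame(y = y,
             effective_group = stats::relevel(factor(panel[[group_col]]),
                                              ref = refg),
             region_id = factor(panel$region_id),
             stringsAsFactors = FALSE)
}

.infer_type <- function(panel, outcome, type) {
  if (!is.null(type)) return(match.arg(type, c("continuous", "binary")))
  ot <- outcome_types(panel)
  if (!is.null(ot) && outcome %in% names(ot)) return(unname(ot[[outcome]]))
  stop("outcome type not declared; pass type = \"continuous\" or \"binary\"",
       call. = FALSE)
}

#' Fit a random-intercept multilevel model
#'
#' Two-level model with persons nested in regions: the outcome is regressed
#' on the group dummies (reference = most populated group) with a regional
#' random intercept `u_j ~ N(0, tau^2)`. Continuous outcomes are
#' log-transformed and fitted by REML (`lme4::lmer`); binary outcomes are
#' fitted as logit-link binomial models by adaptive Gauss-Hermite quadrature
#' (`lme4::glmer`, default 7 nodes). The unconditional-means (null) model is
#' fitted alongside and supplies the variance components for the intraclass
#' correlation as well as the null likelihood for pseudo-R-squared.
#'
#' @param panel a `patient_panel`.
#' @param outcome outcome column name.
#' @param type `"continuous"` or `"binary"`; defaults to the panel's declared
#'   outcome type.
#' @param group_col group dummy column (default `effective_group`, the
#'   output of [aggregate_small_popgroups()]).
#' @param log_offset offset for the log transform of continuous outcomes
#'   (default 1).
#' @param nAGQ adaptive quadrature nodes for binary fits (default 7).
#' @return A `multilevel_fit` with fixed effects, variance components,
#'   empirical-Bayes regional intercept predictions with standard errors,
#'   log-likelihoods of the model and the null model, and the ICC
#'   decomposition.
#' @export
fit_random_intercept <- function(panel, outcome, type = NULL,
                                 group_col = "effective_group",
                                 log_offset = 1, nAGQ = 7L) {
  type <- .infer_type(panel, outcome, type)
  df <- .model_frame(panel, outcome, type, group_col, log_offset)
  if (nlevels(df$region_id) < 2L)
    stop("at least 2 regions required", call. = FALSE)
  # a single group level degenerates to the unconditional means model
  fml <- if (nlevels(df$effective_group) >= 2L)
    y ~ effective_group + (1 | region_id)
  else
    y ~ 1 + (1 | region_id)
  if (type == "continuous") {
    model <- lme4::lmer(fml, data = df, REML = TRUE)
    null_model <- lme4::lmer(y ~ 1 + (1 | region_id), data = df, REML = TRUE)
  } else {
    model <- lme4::glmer(fml, data = df,
                         family = stats::binomial(), nAGQ = nAGQ,
                         control = .glmer_control())
    null_model <- lme4::glmer(y ~ 1 + (1 | region_id), data = df,
                              family = stats::binomial(), nAGQ = nAGQ,
                              control = .glmer_control())
  }
  .check_convergence(model); .check_convergence(null_model)
  .build_fit(model, null_model, df, outcome, type,
             reference_group = levels(df$effective_group)[1L],
             log_offset = if (type == "continuous") log_offset else NA_real_,
             covariate_names = character())
}

#' Fit a multilevel model with regional covariates
#'
#' Extends the random-intercept model with region-level covariates `Z_j`
#' (demographic, supply-side, urbanization, deprivation). Each covariate
#' enters either with a fixed slope only, or with a regional random slope in
#' addition. Covariates are z-standardized across regions before entry so
#' their fixed effects are comparable; a covariate that is constant across
#' regions is rejected (a column that is identically zero is tolerated and
#' dropped as aliased, reducing the fit to the random-intercept model).
#'
#' @inheritParams fit_random_intercept
#' @param region_data a `region_covariates` table covering every region in
#'   the panel.
#' @param covariates names of covariate columns to enter.
#' @param slope_mode `"fixed"` or `"random"`, either a single value for all
#'   covariates or a named vector per covariate.
#' @return A `multilevel_fit`; when random slopes are requested the
#'   random-effect (co)variance matrix is in `slope_vcov`.
#' @export
fit_random_slope <- function(panel, outcome, region_data, covariates,
                             slope_mode = "fixed", type = NULL,
                             group_col = "effective_group",
                             log_offset = 1, nAGQ = 7L) {
  type <- .infer_type(panel, outcome, type)
  stopifnot(inherits(region_data, "data.frame"),
            length(covariates) > 0L)
  if (length(slope_mode) == 1L && is.null(names(slope_mode)))
    slope_mode <- stats::setNames(rep(slope_mode, length(covariates)),
                                  covariates)
  bad_mode <- setdiff(slope_mode, c("fixed", "random"))
  if (length(bad_mode) > 0L)
    stop("slope_mode must be 'fixed' or 'random'", call. = FALSE)
  missing_cov <- setdiff(covariates, names(region_data))
  if (length(missing_cov) > 0L)
    stop("covariate(s) not in region table: ",
         paste(missing_cov, collapse = ", "), call. = FALSE)

  df <- .model_frame(panel, outcome, type, group_col, log_offset)
  idx <- match(as.character(df$region_id), region_data$region_id)
  if (any(is.na(idx)))
    stop("region(s) missing from covariate table: ",
         paste(unique(df$region_id[is.na(idx)]), collapse = ", "),
         call. = FALSE)
  for (cv in covariates) {
    z <- region_data[[cv]]
    if (stats::sd(z) == 0) {
      if (all(z == 0)) {
        df[[cv]] <- 0  # aliased with the intercept; dropped by the fitter
        next
      }
      stop("covariate '", cv, "' is constant across regions", call. = FALSE)
    }
    df[[cv]] <- as.numeric(scale(z))[idx]
  }

  rnd <- covariates[slope_mode[covariates] == "random"]
  re_term <- if (length(rnd) > 0L)
    sprintf("(1 + %s | region_id)", paste(rnd, collapse = " + "))
  else
    "(1 | region_id)"
  fixed_terms <- c(if (nlevels(df$effective_group) >= 2L) "effective_group",
                   covariates)
  fml <- stats::as.formula(paste(
    "y ~", paste(fixed_terms, collapse = " + "), "+", re_term))
  if (type == "continuous") {
    model <- lme4::lmer(fml, data = df, REML = TRUE)
    null_model <- lme4::lmer(y ~ 1 + (1 | region_id), data = df, REML = TRUE)
  } else {
    # vector-valued random effects restrict glmer to the Laplace
    # approximation (nAGQ = 1)
    use_nagq <- if (length(rnd) > 0L) 1L else nAGQ
    model <- lme4::glmer(fml, data = df, family = stats::binomial(),
                         nAGQ = use_nagq, control = .glmer_control())
    null_model <- lme4::glmer(y ~ 1 + (1 | region_id), data = df,
                              family = stats::binomial(), nAGQ = use_nagq,
                              control = .glmer_control())
  }
  .check_convergence(model); .check_convergence(null_model)
  .build_fit(model, null_model, df, outcome, type,
             reference_group = levels(df$effective_group)[1L],
             log_offset = if (type == "continuous") log_offset else NA_real_,
             covariate_names = covariates, random_slopes = rnd)
}

#' @export
print.multilevel_fit <- function(x, ...) {
  cat(sprintf("multilevel_fit (%s outcome '%s'): n = %d persons, J = %d regions\n",
              x$type, x$outcome, x$n, x$J))
  cat(sprintf("  grand mean %.4f; %d group effect(s), reference '%s'\n",
              x$gamma00, length(x$group_effects), x$reference_group))
  if (length(x$covariate_effects) > 0L)
    cat("  regional covariates:",
        paste(sprintf("%s=%.4f", names(x$covariate_effects),
                      x$covariate_effects), collapse = ", "), "\n")
  cat(sprintf("  tau^2 = %.4f%s\n", x$tau2,
              if (x$type == "continuous")
                sprintf(", sigma^2 = %.4f", x$sigma2) else ""))
  cat(sprintf("  ICC (unconditional means model) = %.4f\n", x$icc$icc))
  invisible(x)
}

#' Explained-variation statistics for a multilevel fit
#'
#' For log-linear (continuous) fits: the adjusted R-squared of the
#' fixed-effect prediction on the log scale, penalized for the number of
#' fixed-effect predictors, plus the conditional R-squared (fixed + regional
#' random effects) as a secondary statistic. For logistic (binary) fits:
#' Nagelkerke's R-squared from the marginal likelihoods of the model and the
#' unconditional-means null model,
#' `[1 - (L0/L1)^(2/n)] / [1 - L0^(2/n)]`.
#'
#' @param fit a `multilevel_fit`.
#' @return A list: continuous fits carry `r2`, `adjusted_r2`,
#'   `conditional_r2`; binary fits carry `cox_snell_r2`, `nagelkerke_r2`.
#' @export
fit_statistics <- function(fit) {
  stopifnot(inherits(fit, "multilevel_fit"))
  n <- fit$n
  p <- length(fit$fixef) - 1L
  if (n <= p + 1L)
    stop("n must exceed the number of fixed-effect parameters",
         call. = FALSE)
  if (fit$type == "continuous") {
    y <- lme4::getME(fit$model, "y")
    yhat_fixed <- stats::predict(fit$model, re.form = NA)
    yhat_cond <- stats::predict(fit$model)
    sst <- sum((y - mean(y))^2)
    r2 <- 1 - sum((y - yhat_fixed)^2) / sst
    list(r2 = r2,
         adjusted_r2 = 1 - (1 - r2) * (n - 1) / (n - p - 1),
         conditional_r2 = 1 - sum((y - yhat_cond)^2) / sst)
  } else {
    ll1 <- fit$logLik
    ll0 <- fit$null_logLik
    cs <- 1 - exp(2 / n * (ll0 - ll1))
    max_cs <- 1 - exp(2 / n * ll0)
    list(cox_snell_r2 = cs, nagelkerke_r2 = cs / max_cs)
  }
}
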