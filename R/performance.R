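#' Per-region odds ratios from a logistic multilevel fit
#'
#' Exponentiates each region's empirical-Bayes intercept prediction into an
#' odds ratio relative to the average of all regions (OR = 1), with Wald
#' confidence limits on the random-effect prediction scale,
#' `exp(u_hat +/- z * SE)`.
#'
#' @param fit a binary `multilevel_fit`.
#' @param ci_level confidence level (default 0.95).
#' @return A `regional_effect_table` data.frame: `region_id`, `measure`
#'   (`"odds_ratio"`), `value`, `ci_low`, `ci_high`,
#'   `flag_above_average`, `flag_significant`.
#' @export
regional_odds_ratios <- function(fit, ci_level = 0.95) {
  stopifnot(inherits(fit, "multilevel_fit"))
  if (fit$type != "binary")
    stop("odds ratios require a binary-outcome fit", call. = FALSE)
  stopifnot(ci_level > 0, ci_level < 1)
  z <- stats::qnorm(1 - (1 - ci_level) / 2)
  re <- fit$ranef
  out <- data.frame(region_id = re$region_id,
                    measure = "odds_ratio",
                    value = exp(re$u_hat),
                    ci_low = exp(re$u_hat - z * re$se),
                    ci_high = exp(re$u_hat + z * re$se),
                    stringsAsFactors = FALSE)
  performance_flags(structure(out,
                              class = c("regional_effect_table",
                                        "data.frame")))
}

#' Regression-based PopGroup-adjusted O/E ratios
#'
#' For continuous (log-linear) fits: the observed side of the ratio is the
#' region's total predicted outcome including its regional intercept, the
#' expected side the same prediction with the intercept set to 0, both
#' back-transformed from the log scale with the log-normal smearing factor
#' `exp(sigma^2/2)` (which cancels in the ratio). On the log scale this
#' reduces to `exp(u_hat_j)` per region; it is computed from per-person
#' predictions so covariate fits are handled identically.
#'
#' @param fit a continuous `multilevel_fit`.
#' @param panel the panel the fit was computed on (supplies the region of
#'   each person).
#' @return A `regional_effect_table` with `measure = "adjusted_oe"` (no
#'   confidence limits).
#' @export
regression_adjusted_oe <- function(fit, panel) {
  stopifnot(inherits(fit, "multilevel_fit"))
  if (fit$type != "continuous")
    stop("regression-adjusted O/E requires a continuous-outcome fit",
         call. = FALSE)
  region <- as.character(fit$model@frame$region_id)
  missing_regions <- setdiff(unique(region), fit$ranef$region_id)
  if (length(missing_regions) > 0L)
    stop("region(s) missing from fit: ",
         paste(missing_regions, collapse = ", "), call. = FALSE)
  mu_fixed <- stats::predict(fit$model, re.form = NA)
  u <- stats::setNames(fit$ranef$u_hat, fit$ranef$region_id)
  smear <- exp(fit$sigma2 / 2)
  pred_obs <- exp(mu_fixed + u[region]) * smear
  pred_exp <- exp(mu_fixed) * smear
  obs_j <- tapply(pred_obs, region, sum)
  exp_j <- tapply(pred_exp, region, sum)
  out <- data.frame(region_id = names(obs_j),
                    measure = "adjusted_oe",
                    value = oe_ratio(as.numeric(obs_j), as.numeric(exp_j)),
                    ci_low = NA_real_, ci_high = NA_real_,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  performance_flags(structure(out,
                              class = c("regional_effect_table",
                                        "data.frame")))
}

#' Flag regions above/below the national average
#'
#' A value above 1 marks outcome levels above the national average (worse
#' performance for adverse outcomes); where confidence limits are present a
#' region is flagged significant when its interval excludes 1.
#'
#' @param table a `regional_effect_table` (columns `value`, optionally
#'   `ci_low`/`ci_high`).
#' @return The table with logical columns `flag_above_average` and
#'   `flag_significant` (NA without confidence limits).
#' @export
performance_flags <- function(table) {
  stopifnot(is.data.frame(table), "value" %in% names(table))
  table$flag_above_average <- table$value > 1
  table$flag_significant <-
    if (all(c("ci_low", "ci_high") %in% names(table)))
      ifelse(is.na(table$ci_low) | is.na(table$ci_high), NA,
             table$ci_low > 1 | table$ci_high < 1)
    else NA
  table
}
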